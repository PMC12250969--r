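# Versioned on-disk container for extracted multi-view tensors.
# A single RDS file holding the epoch tensor, labels, subject ids, view
# spec and a format-version stamp; written at run time by the extraction
# step and read back by the evaluation step.

MVBN_CONTAINER_VERSION <- "1"

#' Save / load an extracted feature container
#'
#' \code{save_mvbn_dataset} writes an \code{mvbn_dataset} (tensor, labels,
#' subjects, view spec) plus a format-version stamp; \code{load_mvbn_dataset}
#' reads it back, refusing files with an unknown version.
#'
#' @param dataset An \code{mvbn_dataset}.
#' @param path Output/input file path.
#' @return \code{save_mvbn_dataset}: \code{path}, invisibly;
#'   \code{load_mvbn_dataset}: the \code{mvbn_dataset}.
#' @export
save_mvbn_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "mvbn_dataset"))
  saveRDS(list(version = MVBN_CONTAINER_VERSION,
               x = dataset$x, y = as.character(dataset$y),
               subject = dataset$subject,
               view_spec = as.data.frame(dataset$view_spec)),
          path)
  invisible(path)
}

#' @rdname save_mvbn_dataset
#' @export
load_mvbn_dataset <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, MVBN_CONTAINER_VERSION))
    stop("unsupported container version: ", obj$version)
  structure(list(x = obj$x,
                 y = factor(obj$y, levels = MVBN_STAGES),
                 subject = obj$subject,
                 view_spec = view_spec(obj$view_spec$measure,
                                       obj$view_spec$band)),
            class = "mvbn_dataset")
}
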