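#' Feature matrices
#'
#' Both extractors emit the same tabular dialect: one row per feature
#' instant with columns `t_ms` (the instant, aligned to window-end /
#' sampling times), `f1..fN` (one feature per channel) and `label` (integer
#' gesture class, NA when unlabelled), so the classifier is agnostic to
#' which extractor produced its input.
#'
#' @param t_ms numeric vector of feature instants (ms).
#' @param features numeric matrix, rows = instants, cols = channels.
#' @param labels integer labels, one per row.
#' @return A data.frame of class `feature_matrix`.
#' @export
make_feature_matrix <- function(t_ms, features, labels) {
  features <- as.matrix(features)
  stopifnot(length(t_ms) == nrow(features),
            length(labels) == nrow(features))
  df <- data.frame(t_ms = t_ms)
  for (i in seq_len(ncol(features))) df[[paste0("f", i)]] <- features[, i]
  df$label <- as.integer(labels)
  class(df) <- c("feature_matrix", "data.frame")
  df
}

empty_feature_matrix <- function(n_channels) {
  make_feature_matrix(numeric(0),
                      matrix(numeric(0), nrow = 0, ncol = n_channels),
                      integer(0))
}

#' Extract the numeric feature block of a feature matrix
#' @param fm a `feature_matrix`.
#' @return numeric matrix (rows = instants, cols = channels).
#' @export
feature_values <- function(fm) {
  as.matrix(fm[grep("^f[0-9]+$", names(fm), value = TRUE)])
}

#' Read / write the feature CSV dialect (`t_ms,f1..fN,label`)
#' @param fm a `feature_matrix`.
#' @param file CSV path.
#' @return `write_features_csv` returns `file` invisibly; `read_features_csv`
#'   returns a `feature_matrix`.
#' @export
write_features_csv <- function(fm, file) {
  utils::write.csv(as.data.frame(fm), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(file) {
  df <- utils::read.csv(file)
  fcols <- grep("^f[0-9]+$", names(df), value = TRUE)
  make_feature_matrix(df$t_ms, as.matrix(df[fcols]), df$label)
}
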