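#' Construct a labelled spectra set
#'
#' A `spectra_set` bundles an n x d absorbance matrix with its wavenumber
#' grid, class labels and sample identifiers, and validates the pieces
#' against each other.
#'
#' @param absorbance numeric n x d matrix of absorbance values.
#' @param wavenumbers numeric vector of d channel positions (cm^-1),
#'   strictly monotone (ascending or descending). Kept exactly as given;
#'   NIR instruments commonly scan 10000 -> 4000 cm^-1, i.e. descending.
#' @param labels vector (coerced to factor) of n class labels; every
#'   level must occur at least once.
#' @param sample_ids character vector of n unique identifiers; defaults
#'   to `"s1" ... "sn"`.
#'
#' @return An object of class `spectra_set`: a list with elements
#'   `absorbance`, `wavenumbers`, `labels`, `sample_ids`.
#' @examples
#' x <- spectra_set(matrix(rnorm(12), 3, 4), c(9000, 8000, 7000, 6000),
#'                  labels = c("a", "a", "b"))
#' x
#' @export
spectra_set <- function(absorbance, wavenumbers, labels, sample_ids = NULL) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  wavenumbers <- as.numeric(wavenumbers)
  n <- nrow(absorbance)
  d <- ncol(absorbance)
  if (length(wavenumbers) != d)
    stop("length(wavenumbers) [", length(wavenumbers),
         "] must equal ncol(absorbance) [", d, "]")
  if (length(labels) != n)
    stop("length(labels) [", length(labels),
         "] must equal nrow(absorbance) [", n, "]")
  if (anyNA(absorbance) || !all(is.finite(absorbance)))
    stop("absorbance contains missing or non-finite values")
  if (d >= 2) {
    dw <- diff(wavenumbers)
    if (!(all(dw > 0) || all(dw < 0)))
      stop("wavenumbers must be strictly monotone (all increasing or all decreasing)")
  }
  labels <- factor(labels)
  if (anyNA(labels)) stop("labels contain missing values")
  if (any(table(labels) < 1L)) stop("every class must have at least one sample")
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n) stop("sample_ids must have one entry per sample")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  dimnames(absorbance) <- NULL
  structure(list(absorbance = absorbance, wavenumbers = wavenumbers,
                 labels = labels, sample_ids = sample_ids),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("Labelled spectra set: ", nrow(x$absorbance), " samples x ",
      ncol(x$absorbance), " channels\n", sep = "")
  cat("  wavenumbers: ", format(x$wavenumbers[1]), " .. ",
      format(x$wavenumbers[length(x$wavenumbers)]), " cm^-1\n", sep = "")
  tab <- table(x$labels)
  cat("  classes (", length(tab), "): ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

#' Subset a spectra set by sample index
#'
#' @param x a `spectra_set`.
#' @param i integer or logical sample index.
#' @param ... ignored.
#' @return A `spectra_set` containing the selected samples. Factor levels
#'   of the labels are dropped if a class disappears.
#' @export
`[.spectra_set` <- function(x, i, ...) {
  spectra_set(x$absorbance[i, , drop = FALSE], x$wavenumbers,
              droplevels(x$labels[i]), x$sample_ids[i])
}

#' Read labelled spectra from a wide CSV file
#'
#' The dialect is one row per sample: first column `sample_id`, second
#' column `label`, remaining columns absorbance values with the
#' wavenumber (cm^-1) as column header. [write_spectra()] emits the same
#' dialect, and a write/read round trip reproduces the data to within
#' numeric print precision.
#'
#' @param path path to a CSV file (UTF-8, comma separated, header row).
#' @param label_column name of the label column (default `"label"`).
#' @param id_column name of the sample-id column (default `"sample_id"`).
#' @return A validated [spectra_set()].
#' @export
read_spectra <- function(path, label_column = "label", id_column = "sample_id") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!label_column %in% names(df))
    stop("label column '", label_column, "' not found in ", path)
  keep <- setdiff(names(df), c(label_column, id_column))
  if (length(keep) == 0L) stop("no absorbance channels found in ", path)
  wn <- suppressWarnings(as.numeric(keep))
  if (anyNA(wn))
    stop("non-numeric wavenumber header(s): ",
         paste(keep[is.na(wn)][seq_len(min(3, sum(is.na(wn))))], collapse = ", "))
  block <- df[keep]
  for (j in seq_along(block)) {
    col <- block[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        stop("non-numeric absorbance at row ", bad[1], ", column '", keep[j], "'")
      block[[j]] <- num
    }
  }
  mat <- as.matrix(block)
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop("missing absorbance at row ", idx[1], ", column '", keep[idx[2]], "'")
  }
  labs <- df[[label_column]]
  if (anyNA(labs) || any(!nzchar(as.character(labs))))
    stop("missing label at row ",
         which(is.na(labs) | !nzchar(as.character(labs)))[1])
  ids <- if (id_column %in% names(df)) as.character(df[[id_column]]) else NULL
  spectra_set(mat, wn, labs, ids)
}

#' Write labelled spectra to a wide CSV file
#'
#' @param x a `spectra_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [read_spectra()] for the dialect.
#' @export
write_spectra <- function(x, path) {
  stopifnot(inherits(x, "spectra_set"))
  df <- data.frame(sample_id = x$sample_ids, label = as.character(x$labels),
                   stringsAsFactors = FALSE, check.names = FALSE)
  block <- as.data.frame(x$absorbance)
  names(block) <- format(x$wavenumbers, trim = TRUE, scientific = FALSE, digits = 15)
  utils::write.csv(cbind(df, block), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stratified train/test split
#'
#' Randomly partitions the samples within each class, taking
#' `round(train_fraction * class size)` samples per class for training —
#' so 6 classes of 60 at fraction 0.7 give exactly 252 training and 108
#' test samples. Deterministic given `seed`; the per-class counts do not
#' depend on the seed.
#'
#' @param x a `spectra_set`, or a factor/vector of class labels.
#' @param train_fraction fraction in (0, 1] of each class assigned to
#'   the training set.
#' @param seed integer seed for the random permutation.
#' @return A list of class `split_result` with integer vectors
#'   `train_indices` and `test_indices` (disjoint, jointly exhaustive),
#'   plus `train_fraction` and `seed`.
#' @examples
#' labs <- rep(letters[1:6], each = 60)
#' sp <- stratified_split(labs, 0.7, seed = 1)
#' length(sp$train_indices)  # 252
#' @export
stratified_split <- function(x, train_fraction = 0.7, seed = 1L) {
  labels <- if (inherits(x, "spectra_set")) x$labels else factor(x)
  if (length(labels) == 0L) stop("cannot split an empty dataset")
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction > 1)
    stop("train_fraction must be in (0, 1]")
  rng <- .with_seed(seed, lapply(split(seq_along(labels), labels),
                                 function(idx) idx[sample.int(length(idx))]))
  train <- integer(0)
  for (idx in rng) {
    n_tr <- round(train_fraction * length(idx))
    train <- c(train, idx[seq_len(n_tr)])
  }
  train <- sort(train)
  test <- setdiff(seq_along(labels), train)
  structure(list(train_indices = train, test_indices = test,
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat("Stratified split: ", length(x$train_indices), " train / ",
      length(x$test_indices), " test (fraction ", x$train_fraction,
      ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
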