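#' Coformer candidate libraries
#'
#' A coformer library is a tibble with one row per candidate molecule and a
#' fixed column contract: `id` (unique identifier), `smiles` (structure as a
#' SMILES string), the three physicochemical descriptors `mw` (molecular
#' weight, g/mol), `hbd` (hydrogen-bond donor count), `tpsa` (topological
#' polar surface area, A^2), the bioactivity annotation `tyr_inhib`
#' (tyrosinase-inhibitory potential, scaled to \[0, 1\]), an optional binary
#' suitability `label` (1 = suitable partner) and a `descriptor_source` flag
#' (`"supplied"` or `"computed"`). Descriptor columns may contain `NA` for
#' values still to be computed from structure; labels may be `NA` only for
#' unlabeled candidate pools (training functions reject them).
#'
#' @param data A data frame with at least `id` and `smiles` columns.
#' @param metadata Optional named list recorded as library provenance
#'   (e.g. generator name, seed, configuration).
#'
#' @return A `coformer_library` tibble.
#' @examples
#' lib <- coformer_library(tibble::tibble(
#'   id = c("a", "b"), smiles = c("CCO", "NCC(=O)O"),
#'   mw = c(46.07, 75.07), hbd = c(1, 2), tpsa = c(20.23, 63.32),
#'   tyr_inhib = c(0.2, 0.7), label = c(0L, 1L)
#' ))
#' lib
#' @export
coformer_library <- function(data, metadata = list()) {
  stopifnot(is.data.frame(data))
  data <- as_tibble(data)
  required <- c("id", "smiles")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "coformerscout_format_error")
  }
  optional <- c(mw = NA_real_, hbd = NA_real_, tpsa = NA_real_,
                tyr_inhib = NA_real_)
  for (nm in names(optional)) {
    if (!nm %in% names(data)) data[[nm]] <- optional[[nm]]
    data[[nm]] <- as.double(data[[nm]])
  }
  if (!"label" %in% names(data)) data$label <- NA_integer_
  if (!"descriptor_source" %in% names(data)) {
    data$descriptor_source <- "supplied"
  }
  data$id <- as.character(data$id)
  data$smiles <- as.character(data$smiles)
  lab <- data$label
  if (is.logical(lab)) lab <- as.integer(lab)
  if (!is.numeric(lab)) {
    abort("label column must be numeric 0/1", class = "coformerscout_validation_error")
  }
  bad_lab <- which(!is.na(lab) & !lab %in% c(0, 1))
  if (length(bad_lab)) {
    abort(paste0("label outside {0, 1} in row(s): ",
                 paste(bad_lab, collapse = ", ")),
          class = "coformerscout_validation_error")
  }
  data$label <- as.integer(lab)
  data <- data[, c("id", "smiles", "mw", "hbd", "tpsa", "tyr_inhib",
                   "label", "descriptor_source")]
  out <- new_tibble(data, class = "coformer_library",
                    metadata = metadata, nrow = nrow(data))
  validate_coformer_library(out)
}

#' Validate a coformer library
#'
#' Checks the container invariants: unique non-missing ids, non-empty SMILES,
#' positive molecular weight, non-negative integer HBD counts, non-negative
#' TPSA, `tyr_inhib` within \[0, 1\] and labels within \{0, 1\}. `NA`
#' descriptor entries are allowed (they mark values still to be computed).
#'
#' @param lib A `coformer_library`.
#' @return `lib`, invisibly unchanged, or an error naming the offending rows.
#' @export
validate_coformer_library <- function(lib) {
  stopifnot(is.data.frame(lib))
  fail <- function(rows, what) {
    abort(paste0(what, " in row(s): ", paste(rows, collapse = ", ")),
          class = "coformerscout_validation_error")
  }
  if (anyNA(lib$id)) fail(which(is.na(lib$id)), "missing id")
  if (anyDuplicated(lib$id)) {
    fail(which(duplicated(lib$id)), "duplicate id")
  }
  bad <- which(is.na(lib$smiles) | !nzchar(lib$smiles))
  if (length(bad)) fail(bad, "empty smiles")
  bad <- which(!is.na(lib$mw) & lib$mw <= 0)
  if (length(bad)) fail(bad, "non-positive mw")
  bad <- which(!is.na(lib$hbd) & (lib$hbd < 0 | lib$hbd != floor(lib$hbd)))
  if (length(bad)) fail(bad, "hbd not a non-negative integer")
  bad <- which(!is.na(lib$tpsa) & lib$tpsa < 0)
  if (length(bad)) fail(bad, "negative tpsa")
  bad <- which(!is.na(lib$tyr_inhib) &
                 (lib$tyr_inhib < 0 | lib$tyr_inhib > 1))
  if (length(bad)) fail(bad, "tyr_inhib outside [0, 1]")
  bad <- which(!is.na(lib$label) & !lib$label %in% c(0L, 1L))
  if (length(bad)) fail(bad, "label outside {0, 1}")
  lib
}

#' Library metadata
#' @param lib A `coformer_library`.
#' @return The provenance metadata list attached to the library.
#' @export
library_metadata <- function(lib) attr(lib, "metadata") %||% list()

lib_columns <- c("id", "smiles", "mw", "hbd", "tpsa", "tyr_inhib",
                 "label", "descriptor_source")

#' Read a coformer library from CSV
#'
#' The on-disk format is comma-separated UTF-8 with a mandatory header and
#' `.` decimal separator. `id` and `smiles` are required; descriptor and
#' label columns are optional and default to `NA` (marked for later
#' computation). Malformed rows are rejected with row-number diagnostics.
#'
#' @param path Path to a CSV file.
#' @return A [coformer_library()].
#' @export
read_coformer_library <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "coformerscout_io_error")
  }
  spec <- readr::cols(
    id = readr::col_character(),
    smiles = readr::col_character(),
    mw = readr::col_double(),
    hbd = readr::col_double(),
    tpsa = readr::col_double(),
    tyr_inhib = readr::col_double(),
    label = readr::col_integer(),
    descriptor_source = readr::col_character(),
    .default = readr::col_skip()
  )
  dat <- suppressWarnings(
    readr::read_csv(path, col_types = spec, progress = FALSE,
                    na = c("", "NA"))
  )
  prob <- readr::problems(dat)
  if (nrow(prob) > 0) {
    abort(paste0("malformed CSV row(s): ",
                 paste(unique(prob$row), collapse = ", ")),
          class = "coformerscout_format_error")
  }
  hdr <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                               progress = FALSE))
  missing_cols <- setdiff(c("id", "smiles"), hdr)
  if (length(missing_cols)) {
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "coformerscout_format_error")
  }
  coformer_library(dat, metadata = list(source = path))
}

#' Write a coformer library to CSV
#'
#' Columns are written in the fixed contract order so that
#' `write_coformer_library()` and [read_coformer_library()] round-trip.
#'
#' @param lib A `coformer_library`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coformer_library <- function(lib, path) {
  lib <- validate_coformer_library(coformer_library(lib,
                                                    library_metadata(lib)))
  out <- as_tibble(lib)[, lib_columns]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Split a library into training and test sets
#'
#' Reproducible partition of a labeled library, by default stratified by the
#' suitability label so that small libraries keep their class balance in both
#' halves. With `train_size = 120` on a 159-entry library this yields the
#' conventional 120/39 partition used for model fitting and held-out
#' evaluation.
#'
#' @param lib A `coformer_library`.
#' @param train_size Number of records assigned to the training set.
#' @param seed Integer seed; the same seed always yields the same split.
#' @param stratified Stratify by `label` (default `TRUE`). Requires all
#'   records to be labeled.
#' @return A `data_split` object holding `train_ids`, `test_ids`, `seed`
#'   and `stratified`.
#' @examples
#' lib <- generate_library(generator_config(n = 159, seed = 11))
#' sp <- split_library(lib, train_size = 120, seed = 7)
#' length(sp$test_ids) # 39
#' @export
split_library <- function(lib, train_size, seed = 1L, stratified = TRUE) {
  validate_coformer_library(lib)
  n <- nrow(lib)
  assert_that(is_count(train_size) && train_size <= n,
              paste0("train_size must be an integer in [0, ", n, "]"),
              class = "coformerscout_argument_error")
  ids <- lib$id
  if (stratified) {
    if (anyNA(lib$label)) {
      abort("stratified split requires every record to be labeled",
            class = "coformerscout_validation_error")
    }
    train_ids <- withr::with_seed(seed, {
      classes <- split(ids, lib$label)
      # largest-remainder apportionment of train_size across classes
      quota <- train_size * vapply(classes, length, 0L) / n
      take <- floor(quota)
      rem <- train_size - sum(take)
      if (rem > 0) {
        extra <- order(quota - take, decreasing = TRUE)[seq_len(rem)]
        take[extra] <- take[extra] + 1L
      }
      unlist(Map(function(cl_ids, k) {
        if (k > length(cl_ids)) k <- length(cl_ids)
        sample(cl_ids, k)
      }, classes, take), use.names = FALSE)
    })
    # guard against a class smaller than its quota
    short <- train_size - length(train_ids)
    if (short > 0) {
      pool <- setdiff(ids, train_ids)
      train_ids <- c(train_ids,
                     withr::with_seed(seed + 1L, sample(pool, short)))
    }
  } else {
    train_ids <- withr::with_seed(seed, sample(ids, train_size))
  }
  train_ids <- ids[ids %in% train_ids]   # restore library order
  structure(
    list(train_ids = train_ids,
         test_ids = ids[!ids %in% train_ids],
         seed = as.integer(seed),
         stratified = isTRUE(stratified)),
    class = "data_split"
  )
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("<data_split> %d train / %d test (seed %d, %s)\n",
              length(x$train_ids), length(x$test_ids), x$seed,
              if (x$stratified) "stratified" else "random"))
  invisible(x)
}

#' Extract the records of one side of a split
#'
#' @param lib The `coformer_library` the split was made from.
#' @param split A `data_split`.
#' @param set `"train"` or `"test"`.
#' @return A `coformer_library` with the selected records, in library order.
#' @export
split_records <- function(lib, split, set = c("train", "test")) {
  set <- match.arg(set)
  keep <- if (set == "train") split$train_ids else split$test_ids
  out <- as_tibble(lib)[lib$id %in% keep, ]
  coformer_library(out, metadata = c(library_metadata(lib),
                                     list(subset = set)))
}

#' @export
tidy.data_split <- function(x, ...) {
  tibble(id = c(x$train_ids, x$test_ids),
         set = rep(c("train", "test"),
                   c(length(x$train_ids), length(x$test_ids))))
}
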