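#' Build a normalized feature matrix from a library
#'
#' Assembles the model design matrix: one row per record in library order,
#' one column per requested feature in the given order, z-score normalized
#' column-wise with the sample (n - 1) standard deviation. Constant columns
#' are mapped to zero rather than dividing by zero. The feature `smiles_enc`
#' expands into `k` hashed-fragment count columns (see [encode_smiles()]).
#' The normalization parameters are stored on the result so the same scaling
#' can be re-applied to new candidates at prediction time.
#'
#' @param lib A `coformer_library` with the needed descriptors present.
#' @param features Character vector drawn from
#'   `c("mw", "hbd", "tpsa", "tyr_inhib", "smiles_enc")`.
#' @param k Bucket count for the `smiles_enc` expansion.
#' @param encode_seed Hash salt for the `smiles_enc` expansion.
#' @param scaling Optional `feature_matrix` whose stored normalization is
#'   re-applied (prediction-time use); by default scaling is fit to `lib`.
#' @return A `feature_matrix` object: list with the numeric matrix `x`,
#'   record `ids`, the feature `spec`, and per-column `center` and `scale`.
#' @examples
#' lib <- generate_library(generator_config(n = 20, seed = 3))
#' fm <- featurize_library(lib, c("mw", "hbd", "tpsa", "tyr_inhib"))
#' round(colMeans(fm$x), 12)
#' @export
featurize_library <- function(lib,
                              features = c("mw", "hbd", "tpsa", "tyr_inhib"),
                              k = 32L, encode_seed = 0L, scaling = NULL) {
  validate_coformer_library(lib)
  allowed <- c("mw", "hbd", "tpsa", "tyr_inhib", "smiles_enc")
  bad <- setdiff(features, allowed)
  assert_that(length(bad) == 0,
              paste0("unknown feature(s): ", paste(bad, collapse = ", ")),
              class = "coformerscout_argument_error")
  cols <- list()
  for (f in features) {
    if (f == "smiles_enc") {
      enc <- encode_smiles(lib$smiles, k = k, seed = encode_seed)
      cols[[f]] <- enc
    } else {
      v <- lib[[f]]
      if (anyNA(v)) {
        abort(paste0("missing descriptor '", f, "' for record(s): ",
                     paste(lib$id[is.na(v)], collapse = ", ")),
              class = "coformerscout_validation_error")
      }
      cols[[f]] <- matrix(v, ncol = 1, dimnames = list(NULL, f))
    }
  }
  x_raw <- do.call(cbind, cols)
  rownames(x_raw) <- lib$id
  if (is.null(scaling)) {
    center <- colMeans(x_raw)
    scale_ <- apply(x_raw, 2, sd)
  } else {
    stopifnot(inherits(scaling, "feature_matrix"))
    assert_that(identical(colnames(scaling$x), colnames(x_raw)),
                "feature columns do not match the supplied scaling",
                class = "coformerscout_schema_error")
    center <- scaling$center
    scale_ <- scaling$scale
  }
  safe <- ifelse(is.na(scale_) | scale_ == 0, 1, scale_)
  x <- sweep(sweep(x_raw, 2, center), 2, safe, "/")
  x[, scale_ == 0 | is.na(scale_)] <- 0
  structure(list(x = x, x_raw = x_raw, ids = lib$id,
                 spec = features, k = as.integer(k),
                 encode_seed = as.integer(encode_seed),
                 center = center, scale = scale_),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d records x %d columns (%s)\n",
              nrow(x$x), ncol(x$x), paste(x$spec, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.feature_matrix <- function(x, ...) {
  out <- as_tibble(x$x)
  dplyr::bind_cols(tibble(id = x$ids), out)
}

# Normalize a raw descriptor matrix with a feature_matrix's stored scaling.
apply_scaling <- function(fm, x_raw) {
  stopifnot(inherits(fm, "feature_matrix"))
  x_raw <- as.matrix(x_raw)
  assert_that(ncol(x_raw) == ncol(fm$x),
              "column count does not match the training features",
              class = "coformerscout_schema_error")
  safe <- ifelse(is.na(fm$scale) | fm$scale == 0, 1, fm$scale)
  x <- sweep(sweep(x_raw, 2, fm$center), 2, safe, "/")
  x[, fm$scale == 0 | is.na(fm$scale)] <- 0
  colnames(x) <- colnames(fm$x)
  x
}
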