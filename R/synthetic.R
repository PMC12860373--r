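#' Planted decision rule for synthetic libraries
#'
#' The ground truth used by the synthetic generator: a record is a suitable
#' partner iff all four axis-aligned thresholds hold (closed bounds), namely
#' `hbd` within `hbd_range`, `tpsa` within `tpsa_range`, `mw <= mw_cap` and
#' `tyr_inhib >= tyr_min`. The defaults outline the chemical profile of a
#' small hydrophilic, bioactive coformer, centred on the tranexamic-acid
#' region of descriptor space.
#'
#' @param hbd_range,tpsa_range Closed two-sided bounds.
#' @param mw_cap Upper molecular-weight cap (g/mol).
#' @param tyr_min Minimum tyrosinase-inhibitory score.
#' @return A `planted_rule` list.
#' @export
planted_rule_spec <- function(hbd_range = c(1, 4), tpsa_range = c(20, 90),
                              mw_cap = 250, tyr_min = 0.5) {
  structure(list(hbd_range = hbd_range, tpsa_range = tpsa_range,
                 mw_cap = mw_cap, tyr_min = tyr_min),
            class = "planted_rule")
}

#' Apply the planted rule to records
#'
#' @param records A data frame with `mw`, `hbd`, `tpsa`, `tyr_inhib`
#'   columns (e.g. a `coformer_library`).
#' @param rule A [planted_rule_spec()].
#' @return A tibble with `label` (1 iff every threshold holds, closed
#'   bounds) and `score`, a continuous margin (sum over the four thresholds
#'   of the span-normalized signed distance to the nearest bound; positive
#'   margins mean comfortably inside). The score orders candidates by how
#'   deeply they satisfy the rule; the label equals `score`-wise
#'   feasibility of every component, not a threshold on the sum.
#' @export
planted_rule <- function(records, rule = planted_rule_spec()) {
  needed <- c("mw", "hbd", "tpsa", "tyr_inhib")
  miss <- needed[!needed %in% names(records)]
  assert_that(length(miss) == 0,
              paste0("missing descriptor(s): ", paste(miss, collapse = ", ")),
              class = "coformerscout_data_error")
  d <- records[needed]
  if (anyNA(d)) {
    abort("records contain missing descriptors",
          class = "coformerscout_data_error")
  }
  # per-component margins, normalized by a fixed reference span
  m_hbd <- pmin(d$hbd - rule$hbd_range[1], rule$hbd_range[2] - d$hbd) /
    max(1, diff(range(rule$hbd_range)) + 2)
  m_tpsa <- pmin(d$tpsa - rule$tpsa_range[1],
                 rule$tpsa_range[2] - d$tpsa) / 150
  m_mw <- (rule$mw_cap - d$mw) / 325
  m_tyr <- (d$tyr_inhib - rule$tyr_min) / 1
  margins <- cbind(m_hbd, m_tpsa, m_mw, m_tyr)
  tibble(label = as.integer(apply(margins >= 0, 1, all)),
         score = rowSums(margins))
}

#' Synthetic-library generator configuration
#'
#' Defines the study conditions the generator emulates: a small binary-
#' labeled coformer library (default n = 159, the size of the experimental
#' library this screen is modeled on) over a hydrophilic small-molecule
#' descriptor space (mw 75-400 g/mol, hbd 0-6, tpsa 0-150 A^2, tyr_inhib
#' uniform on \[0, 1\]), labeled by the planted rule and corrupted by
#' independent label flips at the configured noise rate. The planted
#' optimum profile mirrors tranexamic acid (mw 157.21, hbd 2, tpsa 63.32)
#' with a high bioactivity score.
#'
#' @param n Library size (default 159).
#' @param class_balance Target fraction of suitable records (default 0.45;
#'   the generator samples each class by rejection to hit it).
#' @param noise Label-flip probability in \[0, 1) (default 0.1).
#' @param ranges Named list of descriptor sampling ranges.
#' @param rule A [planted_rule_spec()].
#' @param optimum Descriptor profile of the planted optimum.
#' @param optimum_margin Minimum rule-score gap between the planted optimum
#'   and every other pool candidate (default 0.05).
#' @param seed Integer seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n = 159L, class_balance = 0.45, noise = 0.1,
                             ranges = list(mw = c(75, 400), hbd = c(0, 6),
                                           tpsa = c(0, 150),
                                           tyr_inhib = c(0, 1)),
                             rule = planted_rule_spec(),
                             optimum = list(mw = 157.21, hbd = 2,
                                            tpsa = 63.32, tyr_inhib = 0.95),
                             optimum_margin = 0.05, seed = 1L) {
  assert_that(is_count(n) && n >= 1, "n must be >= 1",
              class = "coformerscout_argument_error")
  assert_that(noise >= 0 && noise < 1, "noise must lie in [0, 1)",
              class = "coformerscout_argument_error")
  assert_that(class_balance > 0 && class_balance < 1,
              "class_balance must lie in (0, 1)",
              class = "coformerscout_argument_error")
  structure(list(n = as.integer(n), class_balance = class_balance,
                 noise = noise, ranges = ranges, rule = rule,
                 optimum = optimum, optimum_margin = optimum_margin,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Draw m descriptor rows uniformly from the configured ranges, at the
# precision such quantities are reported with (0.01 g/mol and A^2; the
# bioactivity score to 4 decimals).
sample_descriptors <- function(cfg, m) {
  r <- cfg$ranges
  tibble(mw = round(runif(m, r$mw[1], r$mw[2]), 2),
         hbd = as.double(sample(seq(r$hbd[1], r$hbd[2]), m, replace = TRUE)),
         tpsa = round(runif(m, r$tpsa[1], r$tpsa[2]), 2),
         tyr_inhib = round(runif(m, r$tyr_inhib[1], r$tyr_inhib[2]), 4))
}

# Rejection-sample m rows whose rule label equals `want` (0/1).
sample_class <- function(cfg, m, want, max_tries = 200L) {
  out <- NULL
  tries <- 0L
  while (is.null(out) || nrow(out) < m) {
    tries <- tries + 1L
    if (tries > max_tries) {
      abort("class-balance target unsatisfiable under the descriptor ranges",
            class = "coformerscout_generation_error")
    }
    cand <- sample_descriptors(cfg, max(2L * m, 50L))
    keep <- cand[planted_rule(cand, cfg$rule)$label == want, ]
    out <- if (is.null(out)) keep else dplyr::bind_rows(out, keep)
  }
  out[seq_len(m), ]
}

#' Generate a synthetic coformer library
#'
#' Produces `cfg$n` labeled records: descriptors are drawn from the
#' configured ranges (per class, by rejection, to hit the class-balance
#' target), labels are the planted-rule output flipped independently with
#' probability `cfg$noise`, and each record carries a real SMILES string
#' sampled from the bundled molecule pool so the encoding pipeline is
#' exercisable. The generation manifest (config + seed) is embedded in the
#' library metadata.
#'
#' @param cfg A [generator_config()].
#' @return A `coformer_library` of `cfg$n` records.
#' @examples
#' lib <- generate_library(generator_config(n = 159, seed = 7))
#' table(lib$label)
#' @export
generate_library <- function(cfg = generator_config()) {
  pool <- smiles_pool()
  withr::with_seed(cfg$seed, {
    n_pos <- round(cfg$n * cfg$class_balance)
    n_neg <- cfg$n - n_pos
    pos <- sample_class(cfg, n_pos, 1L)
    neg <- sample_class(cfg, n_neg, 0L)
    d <- dplyr::bind_rows(pos, neg)
    d <- d[sample.int(nrow(d)), ]
    truth <- planted_rule(d, cfg$rule)$label
    flip <- runif(cfg$n) < cfg$noise
    lab <- ifelse(flip, 1L - truth, truth)
    smi <- pool$smiles[sample.int(nrow(pool), cfg$n, replace = TRUE)]
    lib <- tibble(id = sprintf("syn%04d", seq_len(cfg$n)),
                  smiles = smi, mw = d$mw, hbd = d$hbd, tpsa = d$tpsa,
                  tyr_inhib = d$tyr_inhib, label = as.integer(lab),
                  descriptor_source = "supplied")
    coformer_library(lib, metadata = list(
      generator = "coformerscout::generate_library",
      config = unclass(cfg), seed = cfg$seed
    ))
  })
}

#' Generate an unlabeled candidate pool with a planted optimum
#'
#' Produces `size` unlabeled candidates for the inverse-design search. One
#' record — at a seeded random position — carries the configured optimum
#' profile (by default the tranexamic-acid-like descriptors with its real
#' SMILES), and every other candidate is resampled until its planted-rule
#' score falls below the optimum's by at least `cfg$optimum_margin`, making
#' the optimum the strict, unique argmax of the rule score over the pool.
#' The optimum's id is recorded in the library metadata as `optimum_id`.
#'
#' @param cfg A [generator_config()].
#' @param size Pool size (>= 1).
#' @return An unlabeled `coformer_library`.
#' @export
generate_candidate_pool <- function(cfg = generator_config(), size = 1000L) {
  assert_that(is_count(size) && size >= 1, "size must be >= 1",
              class = "coformerscout_argument_error")
  opt <- tibble(mw = cfg$optimum$mw, hbd = as.double(cfg$optimum$hbd),
                tpsa = cfg$optimum$tpsa, tyr_inhib = cfg$optimum$tyr_inhib)
  opt_score <- planted_rule(opt, cfg$rule)$score
  pool <- smiles_pool()
  withr::with_seed(cfg$seed + 1L, {
    m <- size - 1L
    d <- sample_descriptors(cfg, max(m, 1L))[seq_len(max(m, 0L)), , drop = FALSE]
    if (m > 0) {
      for (tries in seq_len(200L)) {
        sc <- planted_rule(d, cfg$rule)$score
        high <- sc > opt_score - cfg$optimum_margin
        if (!any(high)) break
        d[high, ] <- sample_descriptors(cfg, sum(high))
        if (tries == 200L) {
          abort("optimum margin unsatisfiable under the descriptor ranges",
                class = "coformerscout_generation_error")
        }
      }
    }
    opt_pos <- sample.int(size, 1L)
    d <- dplyr::bind_rows(utils::head(d, opt_pos - 1L), opt,
                          utils::tail(d, m - opt_pos + 1L))
    smi <- pool$smiles[sample.int(nrow(pool), size, replace = TRUE)]
    ta <- "NCC1CCC(CC1)C(=O)O"
    smi[opt_pos] <- ta
    ids <- sprintf("cand%05d", seq_len(size))
    lib <- tibble(id = ids, smiles = smi, mw = d$mw, hbd = d$hbd,
                  tpsa = d$tpsa, tyr_inhib = d$tyr_inhib,
                  label = NA_integer_, descriptor_source = "supplied")
    coformer_library(lib, metadata = list(
      generator = "coformerscout::generate_candidate_pool",
      config = unclass(cfg), seed = cfg$seed, optimum_id = ids[opt_pos]
    ))
  })
}

#' Default search constraints aligned with the planted chemistry
#'
#' Box constraints matching the hydrophilic-coformer profile of the planted
#' rule, for use with [run_ga()].
#'
#' @param penalty_weight Penalty multiplier lambda (default 1).
#' @return A [constraint_set()].
#' @export
default_constraints <- function(penalty_weight = 1) {
  constraint_set(
    lower = c(mw = 75, hbd = 1, tpsa = 20, tyr_inhib = 0.5),
    upper = c(mw = 250, hbd = 4, tpsa = 90, tyr_inhib = 1),
    penalty_weight = penalty_weight
  )
}

#' Generate a noiseless linearly separable training set
#'
#' Benchmark data for the classifier: points uniform on \[-1, 1\]^p labeled
#' by the sign of a random unit-vector projection, with points closer than
#' `margin` to the separating hyperplane resampled so the classes are
#' separated by a strict margin.
#'
#' @param n Number of points.
#' @param p Dimensionality (default 4).
#' @param margin Minimum distance to the hyperplane (default 0.1).
#' @param seed Integer seed.
#' @return List with matrix `x`, labels `y` and the true normal `w`.
#' @export
generate_separable_data <- function(n = 200L, p = 4L, margin = 0.1,
                                    seed = 1L) {
  withr::with_seed(seed, {
    w <- rnorm(p); w <- w / sqrt(sum(w^2))
    x <- matrix(runif(n * p, -1, 1), n, p)
    repeat {
      proj <- as.numeric(x %*% w)
      close <- abs(proj) < margin
      if (!any(close)) break
      x[close, ] <- matrix(runif(sum(close) * p, -1, 1), sum(close), p)
    }
    colnames(x) <- paste0("x", seq_len(p))
    list(x = x, y = as.integer(as.numeric(x %*% w) > 0), w = w)
  })
}
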