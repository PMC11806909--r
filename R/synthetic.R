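#' Describe a block of co-varying synthetic features
#'
#' Members of a block share one latent standard-normal factor per sample,
#' so their pairwise rank correlations are strong by construction. With
#' `sign = 1` every member follows the latent factor (all planted edges
#' positive); with `sign = -1` member signs alternate (+, -, +, ...), so
#' opposite-sign members are planted as negative edges — emulating, e.g.,
#' competing taxon guilds.
#'
#' @param size Number of features in the block (>= 2).
#' @param sign `+1` or `-1`, see above.
#' @param latent_noise_sd Standard deviation of the independent Gaussian
#'   noise added to each member on top of the latent factor. 0 plants exact
#'   rank correlations; the default 0.3 gives within-block correlations of
#'   roughly 0.9, comfortably above the usual 0.8 edge threshold.
#' @return A `corr_block` list.
#' @export
corr_block <- function(size, sign = 1, latent_noise_sd = 0.3) {
  size <- assert_count(size, "size", lower = 2L)
  if (!sign %in% c(-1, 1)) {
    abort("`sign` must be +1 or -1.")
  }
  assert_scalar_number(latent_noise_sd, "latent_noise_sd", lower = 0)
  structure(list(size = size, sign = sign, latent_noise_sd = latent_noise_sd),
            class = "corr_block")
}

#' Design for a synthetic feature table with planted correlation structure
#'
#' The generator emulates the statistical structure a co-occurrence
#' pipeline assumes: groups of co-varying features (blocks) plus
#' independent noise features, sampled per-sample from Gaussian latent
#' factors. Default: 30 samples, two positive blocks of 4, and 8 noise
#' features (16 features total).
#'
#' @param n_samples Number of samples (>= 5; default 30).
#' @param blocks List of [corr_block()]s (may be empty).
#' @param n_noise_features Independent standard-normal features appended
#'   after the blocks (default 8).
#' @param seed Integer seed; generation is deterministic per seed.
#' @return A `synthetic_design` list; total features =
#'   `sum(block sizes) + n_noise_features`.
#' @export
synthetic_design <- function(n_samples = 30,
                             blocks = list(corr_block(4), corr_block(4)),
                             n_noise_features = 8,
                             seed = NULL) {
  n_samples <- assert_count(n_samples, "n_samples", lower = 5L)
  n_noise_features <- assert_count(n_noise_features, "n_noise_features", lower = 0L)
  if (!is.list(blocks) || !all(vapply(blocks, inherits, logical(1L), "corr_block"))) {
    abort("`blocks` must be a list of corr_block() objects.")
  }
  p <- sum(vapply(blocks, `[[`, integer(1L), "size")) + n_noise_features
  if (p < 1L) {
    abort("The design must contain at least one feature.")
  }
  structure(
    list(n_samples = n_samples, blocks = blocks,
         n_noise_features = n_noise_features, seed = seed, n_features = p),
    class = "synthetic_design"
  )
}

#' Generate a feature table from a synthetic design
#'
#' Each block draws one latent standard-normal vector over samples; member
#' j of the block is `member_sign_j * latent + N(0, latent_noise_sd)`.
#' Noise features are independent standard normals. Because the network
#' pipeline is rank-based, monotone marginal transforms are irrelevant;
#' `exponentiate = TRUE` applies `exp()` to produce strictly positive
#' "abundance-like" values (identical rank structure) for clr testing.
#'
#' @param design A [synthetic_design()].
#' @param exponentiate Return `exp(values)` instead of raw Gaussians.
#' @return A feature table tibble: `sample_id` `S1..Sn`, block features
#'   first (`F1`, `F2`, ... in block order) then noise features.
#' @examples
#' generate_feature_table(synthetic_design(n_samples = 6, seed = 1))
#' @export
generate_feature_table <- function(design, exponentiate = FALSE) {
  if (!inherits(design, "synthetic_design")) {
    abort("`design` must come from synthetic_design().")
  }
  n <- design$n_samples
  cols <- with_seed(design$seed, {
    out <- list()
    for (blk in design$blocks) {
      latent <- stats::rnorm(n)
      member_signs <- if (blk$sign > 0) {
        rep(1, blk$size)
      } else {
        rep_len(c(1, -1), blk$size)
      }
      for (j in seq_len(blk$size)) {
        noise <- if (blk$latent_noise_sd > 0) {
          stats::rnorm(n, sd = blk$latent_noise_sd)
        } else {
          numeric(n)
        }
        out[[length(out) + 1L]] <- member_signs[j] * latent + noise
      }
    }
    for (j in seq_len(design$n_noise_features)) {
      out[[length(out) + 1L]] <- stats::rnorm(n)
    }
    out
  })
  names(cols) <- paste0("F", seq_along(cols))
  if (exponentiate) {
    cols <- lapply(cols, exp)
  }
  tbl <- tibble(sample_id = paste0("S", seq_len(n)))
  tbl[names(cols)] <- cols
  tbl
}

#' The edges planted by a synthetic design
#'
#' All within-block feature pairs, with the sign implied by the member
#' signs (product of the two members' signs).
#'
#' @param design A [synthetic_design()].
#' @return Tibble `(from, to, sign)` using the generated feature names.
#' @export
planted_edges <- function(design) {
  rows <- list()
  offset <- 0L
  for (blk in design$blocks) {
    member_signs <- if (blk$sign > 0) rep(1, blk$size) else rep_len(c(1, -1), blk$size)
    ids <- paste0("F", offset + seq_len(blk$size))
    for (i in seq_len(blk$size - 1L)) {
      for (j in (i + 1L):blk$size) {
        rows[[length(rows) + 1L]] <-
          tibble(from = ids[i], to = ids[j], sign = member_signs[i] * member_signs[j])
      }
    }
    offset <- offset + blk$size
  }
  if (length(rows) == 0L) {
    return(tibble(from = character(), to = character(), sign = numeric()))
  }
  dplyr::bind_rows(rows)
}

#' Generate two tables sharing a feature space
#'
#' Draws two independent tables (each from its own design and seed) with a
#' common set of feature ids, as needed for paired network comparisons.
#'
#' @param design_a,design_b [synthetic_design()]s with equal total feature
#'   counts.
#' @param ... Passed to [generate_feature_table()].
#' @return List with elements `a` and `b`.
#' @export
generate_paired_tables <- function(design_a, design_b, ...) {
  if (design_a$n_features != design_b$n_features) {
    abort(sprintf("Designs must share the total feature count (%d vs %d).",
                  design_a$n_features, design_b$n_features))
  }
  list(a = generate_feature_table(design_a, ...),
       b = generate_feature_table(design_b, ...))
}
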