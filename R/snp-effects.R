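#' Back-solve marker effects from genomic breeding values
#'
#' Converts the genomic breeding values `a_g` of the genotyped animals into
#' per-marker effects `u = D Z' G^-1 a_g`, where `Z` is the
#' frequency-centered genotype matrix, `D` the diagonal of current marker
#' weights and `G` the (possibly blended, possibly re-weighted) genomic
#' relationship matrix built from the same weights. The realized variance of
#' each marker, `r_i = 2 p_i (1 - p_i) u_i^2`, is returned alongside.
#'
#' @param panel A [marker_panel()] of the genotyped animals.
#' @param a_g Named numeric vector of genomic breeding values, one per panel
#'   individual (any order; matched by name). Unnamed vectors must match the
#'   panel row order.
#' @param weights Marker weights tibble ([marker_weights()] or
#'   [update_weights()]).
#' @param G_star The relationship matrix to invert; defaults to the
#'   unblended `build_G(panel, weights)`.
#' @return A tibble `marker`, `chromosome`, `bp`, `freq`, `d`, `u`, `r`,
#'   `iteration`, with `a_g` stored in attribute `a_g`.
#' @export
backsolve_effects <- function(panel, a_g, weights = marker_weights(panel),
                              G_star = build_G(panel, weights)) {
  stopifnot(inherits(panel, "marker_panel"))
  ids <- rownames(panel$genotypes)
  if (!is.null(names(a_g))) {
    if (!all(ids %in% names(a_g))) abort("`a_g` does not name every panel individual")
    a_g <- a_g[ids]
  } else if (length(a_g) != length(ids)) {
    abort("`a_g` length does not match the panel individuals")
  }
  if (!all(dim(G_star) == length(ids))) abort("G_star does not conform to the panel")

  p <- weights$freq
  Z <- sweep(impute_genotypes(panel), 2, 2 * p)
  sol <- tryCatch(solve(unclass(G_star), a_g),
                  error = function(e) abort("G* is singular; blend with A22 (alpha > 0)"))
  u <- unname(weights$d * drop(crossprod(Z, sol)))
  out <- tibble::tibble(
    marker = panel$map$marker,
    chromosome = panel$map$chromosome,
    bp = panel$map$bp,
    freq = p,
    d = weights$d,
    u = u,
    r = 2 * p * (1 - p) * u^2,
    iteration = weights$iteration[1]
  )
  attr(out, "a_g") <- setNames(as.numeric(a_g), ids)
  out
}

#' Re-weight markers by their realized variances
#'
#' Replaces the expected marker contributions with realized ones: the new
#' weight is proportional to `u_i^2` (so each marker's share of G becomes its
#' realized variance `2 p_i (1 - p_i) u_i^2`), rescaled so that
#' `sum_i d_i * 2 p_i (1 - p_i) = 1`, which keeps G on the scale of the
#' first-iteration expected-variance weighting. Weights that would fall below
#' `floor` times the mean raw weight are raised to that floor before
#' rescaling, preventing a singular re-weighted G when effects shrink to ~0.
#'
#' @param effects Effects tibble from [backsolve_effects()].
#' @param floor Relative weight floor, default `1e-8`.
#' @return A weights tibble (`marker`, `freq`, `d`, `iteration` incremented).
#' @export
update_weights <- function(effects, floor = 1e-8) {
  stopifnot(is.data.frame(effects), all(c("marker", "freq", "u") %in% names(effects)))
  raw <- effects$u^2
  if (all(raw == 0)) abort("all marker effects are zero; cannot re-weight")
  raw <- pmax(raw, floor * mean(raw))
  het <- 2 * effects$freq * (1 - effects$freq)
  d <- raw / sum(raw * het)
  tibble::tibble(marker = effects$marker, freq = effects$freq, d = d,
                 iteration = effects$iteration[1] + 1L)
}

#' Iterative re-weighting of the genomic relationship matrix
#'
#' Round 1 back-solves marker effects under expected-variance weights; each
#' later round re-weights the markers by the previous round's realized
#' variances, rebuilds (and re-blends) G, and re-solves the effects with the
#' breeding values `a_g` held fixed. Four rounds is the conventional point of
#' stabilization.
#'
#' @param panel A [marker_panel()] of the genotyped animals.
#' @param a_g Genomic breeding values (see [backsolve_effects()]).
#' @param n_rounds Number of rounds, default 4.
#' @param A22 Pedigree relationships of the genotyped animals, used for
#'   blending; `NULL` (with `alpha = 0`) skips blending.
#' @param alpha Blending fraction passed to [blend_G()].
#' @param floor Relative weight floor for [update_weights()].
#' @param freq Optional allele frequencies overriding the panel's observed
#'   ones (e.g. base-population frequencies).
#' @return A tibble of all rounds' effects stacked, distinguished by
#'   `iteration` (1 .. `n_rounds`).
#' @export
iterate_reweighting <- function(panel, a_g, n_rounds = 4L, A22 = NULL,
                                alpha = if (is.null(A22)) 0 else 0.05,
                                floor = 1e-8, freq = NULL) {
  n_rounds <- assert_count(n_rounds, "n_rounds")
  if (alpha > 0 && is.null(A22)) abort("blending (alpha > 0) requires A22")
  w <- marker_weights(panel, freq = freq)
  rounds <- vector("list", n_rounds)
  for (k in seq_len(n_rounds)) {
    if (k > 1) w <- update_weights(rounds[[k - 1]], floor = floor)
    G <- build_G(panel, w)
    G_star <- if (alpha > 0) blend_G(G, A22, alpha) else G
    rounds[[k]] <- backsolve_effects(panel, a_g, weights = w, G_star = G_star)
    rounds[[k]]$iteration <- k
  }
  dplyr::bind_rows(rounds)
}

#' Partition realized marker variance into adjacent-SNP windows
#'
#' Tiles each chromosome's marker list into consecutive non-overlapping
#' blocks of `window_size` adjacent SNPs (final partial block retained) and
#' sums the realized variances `2 p (1 - p) u^2` within each block. Shares
#' are normalized genome-wide so they sum to 1. Window IDs run sequentially
#' across the genome. An overlapping sliding mode (step 1) is available for
#' comparison via `sliding = TRUE`; its shares are normalized the same way
#' but windows then share markers.
#'
#' @param effects A single round of effects (one `iteration` value), sorted
#'   by (chromosome block, ascending bp) as produced by the panel map.
#' @param window_size SNPs per window, default 10.
#' @param sliding Use overlapping step-1 windows instead of tiling.
#' @return Tibble `window_id`, `chromosome`, `start_bp`, `stop_bp`,
#'   `n_snps`, `variance`, `variance_share`.
#' @export
window_variance <- function(effects, window_size = 10L, sliding = FALSE) {
  stopifnot(is.data.frame(effects),
            all(c("chromosome", "bp", "r") %in% names(effects)))
  window_size <- assert_count(window_size, "window_size")
  if (length(unique(effects$iteration %||% 1L)) > 1) {
    abort("`effects` mixes several re-weighting rounds; filter one iteration first")
  }
  bad <- unlist(lapply(split(effects$bp, effects$chromosome), is.unsorted))
  if (any(bad)) abort("markers must be sorted by ascending bp within chromosome")

  chr_rle <- rle(effects$chromosome)
  if (any(duplicated(chr_rle$values))) {
    abort("markers of one chromosome must be contiguous in `effects`")
  }

  per_chr <- function(df) {
    nc <- nrow(df)
    starts <- if (sliding) seq_len(max(1L, nc - window_size + 1L)) else {
      seq.int(1L, nc, by = window_size)
    }
    purrr::map_dfr(starts, function(k) {
      idx <- k:min(nc, k + window_size - 1L)
      tibble::tibble(chromosome = df$chromosome[1],
                     start_bp = df$bp[idx[1]], stop_bp = df$bp[idx[length(idx)]],
                     n_snps = length(idx), variance = sum(df$r[idx]))
    })
  }
  chunks <- split(effects, factor(effects$chromosome, levels = chr_rle$values))
  grouped <- purrr::map_dfr(chunks, per_chr)
  tot <- sum(grouped$variance)
  if (tot <= 0) abort("total realized variance is zero; nothing to partition")
  tibble::tibble(window_id = seq_len(nrow(grouped)),
                 chromosome = grouped$chromosome,
                 start_bp = grouped$start_bp, stop_bp = grouped$stop_bp,
                 n_snps = grouped$n_snps, variance = grouped$variance,
                 variance_share = grouped$variance / tot)
}

#' Rank the windows absorbing the most genetic variance
#'
#' @param windows A [window_variance()] table.
#' @param n Number of top windows, default 10. Exact ties are broken by
#'   ascending chromosome, then start position.
#' @return The `n` top rows, sorted by descending variance share, with
#'   `var_pct` (share as a percentage) added.
#' @export
top_windows <- function(windows, n = 10L) {
  stopifnot(is.data.frame(windows), nrow(windows) > 0)
  n <- assert_count(n, "n")
  if (n > nrow(windows)) {
    warn(sprintf("only %d windows available; returning all", nrow(windows)))
    n <- nrow(windows)
  }
  chr_num <- suppressWarnings(as.numeric(windows$chromosome))
  ord <- order(-windows$variance_share,
               if (all(!is.na(chr_num))) chr_num else windows$chromosome,
               windows$start_bp)
  out <- windows[ord[seq_len(n)], ]
  out$var_pct <- 100 * out$variance_share
  out[, c("window_id", "var_pct", "chromosome", "start_bp", "stop_bp",
          "n_snps", "variance", "variance_share")]
}
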