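#' Per-marker weights for the genomic relationship matrix
#'
#' First-iteration weights are the inverse expected marker variances,
#' `d_i = 1 / (m * 2 p_i (1 - p_i))` over the `m` analyzed markers, so that
#' the scale normalization `sum_i d_i * 2 p_i (1 - p_i) = 1` holds exactly
#' and `G = Z D Z'` has mean diagonal near 1 in an unrelated
#' Hardy-Weinberg base population. Later iterations replace the expected
#' contributions with realized variances via [update_weights()], preserving
#' the same normalization.
#'
#' @param panel A [marker_panel()] (uses its `freq`); or pass `freq` directly.
#' @param freq Optional numeric vector overriding the panel frequencies.
#' @return A tibble `marker`, `freq`, `d`, `iteration`.
#' @export
marker_weights <- function(panel, freq = NULL) {
  stopifnot(inherits(panel, "marker_panel"))
  p <- freq %||% panel$freq
  if (any(p <= 0 | p >= 1)) {
    abort("fixed markers (p = 0 or 1) must be removed by QC before weighting")
  }
  m <- length(p)
  het <- 2 * p * (1 - p)
  tibble::tibble(marker = panel$map$marker, freq = p,
                 d = 1 / (m * het), iteration = 1L)
}

#' Weighted genomic relationship matrix G = Z D Z'
#'
#' Genotypes are centered by allele frequency: the -1/0/1 coding minus
#' `(2p - 1)`, equivalently the 0/1/2 coding minus `2p` (VanRaden
#' centering, `E(z) = 0`). Missing calls are mean-imputed (to `2p`) for
#' matrix building only. With first-iteration weights this is the
#' expected-variance-weighted G whose mean diagonal is ~1.
#'
#' @param panel A [marker_panel()] with no fixed markers.
#' @param weights A weights tibble from [marker_weights()] or
#'   [update_weights()]; defaults to first-iteration weights.
#' @return Dense symmetric matrix over the panel individuals, attribute
#'   `kind = "G"` plus the weights iteration in attribute `iteration`.
#' @export
build_G <- function(panel, weights = marker_weights(panel)) {
  stopifnot(inherits(panel, "marker_panel"))
  if (!identical(weights$marker, panel$map$marker)) {
    abort("weights do not match the panel markers")
  }
  p <- weights$freq
  if (any(p <= 0 | p >= 1)) abort("fixed markers (p = 0 or 1) must be filtered before build_G")
  Z <- sweep(impute_genotypes(panel), 2, 2 * p)
  G <- tcrossprod(Z %*% diag(weights$d, nrow = length(weights$d)), Z)
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(panel$genotypes), rownames(panel$genotypes))
  structure(G, kind = "G", iteration = weights$iteration[1])
}

#' Blend G with the pedigree relationships of the genotyped animals
#'
#' `G* = (1 - alpha) G + alpha A22` — the usual positive-definiteness repair
#' that keeps `G*` invertible when G is singular (duplicated genotypes,
#' fewer markers than animals).
#'
#' @param G Genomic relationship matrix.
#' @param A22 Pedigree relationships of the same animals, same order.
#' @param alpha Blending fraction in `[0, 1)`; default 0.05.
#' @return The blended matrix, attribute `kind = "G_blended"`.
#' @export
blend_G <- function(G, A22, alpha = 0.05) {
  assert_fraction(alpha, "alpha", 0, 1, open_hi = TRUE)
  stopifnot(all(dim(G) == dim(A22)))
  if (!is.null(dimnames(G)) && !is.null(dimnames(A22)) &&
      !identical(rownames(G), rownames(A22))) {
    abort("G and A22 must be over the same animals in the same order")
  }
  structure((1 - alpha) * unclass(G) + alpha * unclass(A22),
            kind = "G_blended", alpha = alpha, dimnames = dimnames(G))
}

#' Single-step relationship matrix inverse
#'
#' `H^-1 = A^-1 + [0 0; 0 G*^-1 - A22^-1]`: the pedigree inverse over all
#' animals, corrected in the genotyped block by the difference between the
#' inverse blended genomic matrix and the inverse pedigree relationships of
#' the genotyped animals. Outside the genotyped block H^-1 equals A^-1
#' exactly.
#'
#' @param Ainv Sparse A-inverse over the full pedigree ([build_A_inverse()]).
#' @param G_star Blended genomic matrix over the genotyped animals.
#' @param A22 Pedigree relationship block for the same animals, same order.
#' @return Sparse symmetric `dgCMatrix` with attribute `genotyped` (IDs).
#'   With an empty genotyped set the result is `Ainv` unchanged.
#' @export
build_H_inverse <- function(Ainv, G_star, A22) {
  ids <- rownames(Ainv)
  gids <- rownames(G_star) %||% character(0)
  if (length(gids) == 0 || nrow(G_star) == 0) {
    out <- methods::as(Ainv, "generalMatrix")
    attr(out, "genotyped") <- character(0)
    return(out)
  }
  if (!identical(gids, rownames(A22))) abort("G_star and A22 must share the same animal order")
  if (!all(gids %in% ids)) abort("genotyped IDs must be a subset of the pedigree")
  Ginv <- tryCatch(solve(unclass(G_star)),
                   error = function(e) abort("G* is singular; increase the blending alpha"))
  A22inv <- tryCatch(solve(unclass(A22)),
                     error = function(e) abort("A22 is singular; check the pedigree of the genotyped animals"))
  idx <- match(gids, ids)
  H <- methods::as(Ainv, "CsparseMatrix")
  corr <- Matrix::sparseMatrix(i = rep(idx, each = length(idx)),
                               j = rep(idx, times = length(idx)),
                               x = as.vector(t(Ginv - A22inv)),
                               dims = dim(Ainv), dimnames = dimnames(Ainv))
  out <- methods::as(H + corr, "generalMatrix")
  attr(out, "genotyped") <- gids
  out
}

#' Export a relationship matrix as sorted triplets
#'
#' Writes the upper triangle (including the diagonal) as a TSV
#' `id_i, id_j, value` sorted by (id_i, id_j), for diffing against other
#' tools.
#'
#' @param mat A matrix (dense or sparse) with ID dimnames.
#' @param path Output file.
#' @param zero_tol Entries with `|value| <= zero_tol` are omitted.
#' @return `path`, invisibly.
#' @export
write_relmat_triplets <- function(mat, path, zero_tol = 0) {
  ids <- rownames(mat)
  m <- as.matrix(mat)
  ut <- upper.tri(m, diag = TRUE)
  df <- data.frame(id_i = ids[row(m)[ut]], id_j = ids[col(m)[ut]],
                   value = m[ut], stringsAsFactors = FALSE)
  df <- df[abs(df$value) > zero_tol, ]
  df <- df[order(df$id_i, df$id_j), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
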