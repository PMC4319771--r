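#' Inbreeding coefficients by the Meuwissen–Luo algorithm
#'
#' @param ped A topologically ordered pedigree tibble.
#' @return Named numeric vector of inbreeding coefficients F.
#' @export
pedigree_inbreeding <- function(ped) {
  validate_pedigree(ped)
  n <- nrow(ped)
  s <- match(ped$sire, ped$animal)
  d <- match(ped$dam, ped$animal)
  s[is.na(s)] <- 0L; d[is.na(d)] <- 0L
  f <- numeric(n)     # inbreeding
  dii <- numeric(n)   # within-animal Mendelian sampling variance
  for (i in seq_len(n)) {
    dii[i] <- 0.5 - 0.25 * ((if (s[i] > 0) f[s[i]] else -1) +
                            (if (d[i] > 0) f[d[i]] else -1))
    if (s[i] == 0L && d[i] == 0L) { f[i] <- 0; next }
    # back-propagate the i-th row of the Cholesky factor of A over ancestors;
    # a_ii = sum_j L_ij^2 d_j and F_i = a_ii - 1
    Lrow <- numeric(i)
    Lrow[i] <- 1
    fi <- -1
    for (j in i:1) {
      if (Lrow[j] == 0) next
      if (s[j] > 0) Lrow[s[j]] <- Lrow[s[j]] + 0.5 * Lrow[j]
      if (d[j] > 0) Lrow[d[j]] <- Lrow[d[j]] + 0.5 * Lrow[j]
      fi <- fi + Lrow[j]^2 * dii[j]
      Lrow[j] <- 0
    }
    f[i] <- fi
  }
  setNames(f, ped$animal)
}

#' Pedigree numerator relationship matrix A (tabular method)
#'
#' Dense recursive construction including inbreeding:
#' `a_ij = 0.5 (a_{i,sire(j)} + a_{i,dam(j)})` for `i < j` and
#' `a_jj = 1 + 0.5 a_{sire(j),dam(j)}`. Intended for small to moderate
#' pedigrees (the matrix is dense).
#'
#' @param ped A topologically ordered pedigree tibble.
#' @return A symmetric numeric matrix with animal IDs as dimnames and
#'   attribute `kind = "A"`.
#' @export
build_A <- function(ped) {
  validate_pedigree(ped)
  n <- nrow(ped)
  if (n > 20000) abort("pedigree too large for a dense A; use build_A_inverse / pedigree_A_submatrix")
  s <- match(ped$sire, ped$animal); d <- match(ped$dam, ped$animal)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (j in seq_len(n)) {
    sj <- s[j]; dj <- d[j]
    if (j > 1) {
      i <- seq_len(j - 1L)
      row <- 0.5 * ((if (!is.na(sj)) A[i, sj] else 0) +
                    (if (!is.na(dj)) A[i, dj] else 0))
      A[i, j] <- row
      A[j, i] <- row
    }
    A[j, j] <- 1 + (if (!is.na(sj) && !is.na(dj)) 0.5 * A[sj, dj] else 0)
  }
  structure(A, kind = "A")
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding accounted for via the Mendelian sampling
#' variances `d_i = 0.5 - 0.25 (F_s + F_d)` (a missing parent contributes
#' F = -1), i.e. the Meuwissen–Luo construction `A^{-1} = (I-P)' D^{-1} (I-P)`.
#'
#' @param ped A topologically ordered pedigree tibble.
#' @return A sparse symmetric `dgCMatrix` with animal IDs as dimnames.
#' @export
build_A_inverse <- function(ped) {
  validate_pedigree(ped)
  n <- nrow(ped)
  s <- match(ped$sire, ped$animal); d <- match(ped$dam, ped$animal)
  f <- pedigree_inbreeding(ped)
  dii <- 0.5 - 0.25 * ((ifelse(is.na(s), -1, f[ifelse(is.na(s), 1L, s)])) +
                       (ifelse(is.na(d), -1, f[ifelse(is.na(d), 1L, d)])))
  w <- 1 / dii
  # accumulate triplets in vectorized blocks
  trip_i <- list(); trip_j <- list(); trip_x <- list()
  push <- function(i, j, x) {
    k <- length(trip_i) + 1L
    trip_i[[k]] <<- i; trip_j[[k]] <<- j; trip_x[[k]] <<- x
  }
  idx <- seq_len(n)
  push(idx, idx, w)
  has_s <- !is.na(s); has_d <- !is.na(d)
  push(idx[has_s], s[has_s], -0.5 * w[has_s])
  push(s[has_s], idx[has_s], -0.5 * w[has_s])
  push(idx[has_d], d[has_d], -0.5 * w[has_d])
  push(d[has_d], idx[has_d], -0.5 * w[has_d])
  push(s[has_s], s[has_s], 0.25 * w[has_s])
  push(d[has_d], d[has_d], 0.25 * w[has_d])
  both <- has_s & has_d
  push(s[both], d[both], 0.25 * w[both])
  push(d[both], s[both], 0.25 * w[both])
  Ainv <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                               x = unlist(trip_x), dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  Matrix::drop0(Ainv)
}

#' Submatrix of A for selected animals without forming A
#'
#' Computes columns of `A` by the indirect (Colleau) method: `A x` is
#' evaluated through the pedigree factorization `A = T D T'` in two linear
#' passes, so the block `A[ids, ids]` (e.g. A22 for the genotyped animals)
#' costs `O(n)` per animal regardless of pedigree size.
#'
#' @param ped A topologically ordered pedigree tibble.
#' @param ids Animal IDs selecting the block.
#' @return Dense symmetric matrix `A[ids, ids]` with attribute `kind = "A22"`.
#' @export
pedigree_A_submatrix <- function(ped, ids) {
  validate_pedigree(ped)
  if (!all(ids %in% ped$animal)) abort("`ids` must all be pedigree animals")
  n <- nrow(ped)
  s <- match(ped$sire, ped$animal); d <- match(ped$dam, ped$animal)
  f <- pedigree_inbreeding(ped)
  dii <- 0.5 - 0.25 * ((ifelse(is.na(s), -1, f[ifelse(is.na(s), 1L, s)])) +
                       (ifelse(is.na(d), -1, f[ifelse(is.na(d), 1L, d)])))
  cols <- match(ids, ped$animal)
  out <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (k in seq_along(cols)) {
    x <- numeric(n); x[cols[k]] <- 1
    # w = T' x (backward pass)
    w <- x
    for (i in n:1) {
      if (w[i] != 0) {
        if (!is.na(s[i])) w[s[i]] <- w[s[i]] + 0.5 * w[i]
        if (!is.na(d[i])) w[d[i]] <- w[d[i]] + 0.5 * w[i]
      }
    }
    # q = T (D w) (forward pass)
    q <- dii * w
    for (i in seq_len(n)) {
      acc <- 0
      if (!is.na(s[i])) acc <- acc + 0.5 * q[s[i]]
      if (!is.na(d[i])) acc <- acc + 0.5 * q[d[i]]
      q[i] <- q[i] + acc
    }
    out[, k] <- q[cols]
  }
  structure((out + t(out)) / 2, kind = "A22")
}
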