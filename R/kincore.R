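## kincore: Mendelian-sampling variances, exact small-pedigree oracles
## (tabular A, memoized recursive kinship) and the Cholesky-based F
## algorithms of Meuwissen-Luo (ML) and Sargolzaei-Iwaisaki (SI), plus the
## sparse L-row computation shared with the indirect methods.
##
## Throughout, A = L D L' with L the unit lower-triangular gene-flow matrix
## and D the diagonal of within-family (Mendelian-sampling) variances:
## d_i = 0.5 - 0.25 (F_si + F_di) for a real animal, d_m = gamma_m for a
## metafounder (whose F is gamma - 1).  F_i = A_ii - 1 = sum_k L_ik^2 d_k - 1.

.oracle_cap <- function() getOption("pedmi.oracle_cap", 5000L)

.check_ped <- function(ped) {
  if (!inherits(ped, "pedigree"))
    stop("expected a built pedigree; see build_pedigree()")
  invisible(ped)
}

#' Mendelian-sampling variance
#'
#' The within-family additive genetic variance of a progeny,
#' `0.5 - 0.25 * (F_sire + F_dam)`.  The F of a gamma-metafounder parent is
#' `gamma - 1`, so two gamma = 0 metafounder parents give the founder value
#' 1.
#'
#' @param f_sire,f_dam inbreeding coefficients of the parents (>= -1);
#'   vectorized.
#' @return Numeric vector of variances in `(0, 1]` for admissible inputs.
#' @export
mendelian_variance <- function(f_sire, f_dam) {
  if (any(f_sire < -1, na.rm = TRUE) || any(f_dam < -1, na.rm = TRUE))
    stop("parental inbreeding coefficients must be >= -1")
  0.5 - 0.25 * (f_sire + f_dam)
}

#' Mendelian-sampling variances of a whole pedigree
#'
#' @param ped a built `pedigree`.
#' @param f inbreeding coefficients in sorted order (result of any
#'   [inbreeding()] method) or `NULL` to compute them (via SI).
#' @return Numeric vector `d` of length `ped$n`; metafounders carry their
#'   gamma.
#' @export
d_vector <- function(ped, f = NULL) {
  .check_ped(ped)
  if (is.null(f)) return(cpp_inbreeding_SI(ped$sire, ped$dam, ped$lap,
                                           ped$is_meta, ped$gamma)$d)
  fv <- if (inherits(f, "inbreeding_result")) f$f else f
  d <- numeric(ped$n)
  d[ped$is_meta] <- ped$gamma[ped$is_meta]
  i <- which(!ped$is_meta)
  d[i] <- mendelian_variance(fv[ped$sire[i]], fv[ped$dam[i]])
  d
}

#' Dense numerator relationship matrix (tabular method)
#'
#' The brute-force oracle: builds A row by row with
#' `A_ij = (A_si,j + A_di,j) / 2` and `A_ii = 1 + A_si,di / 2`;
#' metafounders have `A_mm = gamma` and 0 off-diagonals to other
#' metafounders.
#'
#' @param ped a built `pedigree`.
#' @param cap refuse pedigrees larger than this (dense memory guard).
#' @return `n x n` numeric matrix in sorted order.
#' @export
tabular_A <- function(ped, cap = .oracle_cap()) {
  .check_ped(ped)
  if (ped$n > cap)
    stop("pedigree size ", ped$n, " exceeds the dense-oracle cap (", cap, ")")
  A <- cpp_tabular_A(ped$sire, ped$dam, ped$is_meta, ped$gamma)
  dimnames(A) <- list(ped$orig_id, ped$orig_id)
  A
}

#' Memoized recursive additive relationship (REC oracle)
#'
#' `A_ij` by the standard recursion with coefficients stored per pair, so
#' each element is computed once.
#'
#' @param ped a built `pedigree`.
#' @param i,j animal indices in sorted order (vectorized, recycled).
#' @param cap size guard as in [tabular_A()].
#' @return Numeric vector of relationships `A_ij`.
#' @export
kinship_recursive <- function(ped, i, j, cap = .oracle_cap()) {
  .check_ped(ped)
  if (ped$n > cap)
    stop("pedigree size ", ped$n, " exceeds the oracle cap (", cap, ")")
  k <- cbind(as.integer(i), as.integer(j))
  if (any(k < 1L) || any(k > ped$n)) stop("animal index out of range")
  cpp_kinship_pairs(ped$sire, ped$dam, ped$is_meta, ped$gamma,
                    k[, 1], k[, 2])$a
}

#' One sparse row of the Cholesky factor L
#'
#' Traverses the ancestors of `s` in strictly descending LAP order
#' (per-LAP buckets, ascending index within a bucket): start with
#' coefficient 1 at `s`, pop the highest-LAP pending animal, emit its
#' coefficient and push half of it to each parent.  The entries cover
#' exactly `ANC_s`, the ancestors of `s` including `s` itself, and satisfy
#' `sum_k L_sk^2 d_k = 1 + F_s`.
#'
#' @param ped a built `pedigree`.
#' @param s animal index in sorted order.
#' @param f,d optional finalized F and Mendelian-variance vectors; when
#'   given, every ancestor's F must be non-missing (consistency check) and
#'   the row is validated against `1 + F_s`.
#' @return `list(owner, index, coef)` with entries in descending-LAP order.
#' @export
L_row <- function(ped, s, f = NULL, d = NULL) {
  .check_ped(ped)
  s <- as.integer(s)
  if (s < 1L || s > ped$n) stop("animal index out of range")
  row <- cpp_L_row(ped$sire, ped$dam, ped$lap, ped$is_meta, s)
  if (!is.null(f)) {
    fv <- if (inherits(f, "inbreeding_result")) f$f else f
    if (anyNA(fv[row$index]))
      stop("unfinalized inbreeding coefficient among the ancestors of ", s)
    if (is.null(d)) d <- d_vector(ped, fv)
    tot <- sum(row$coef^2 * d[row$index])
    if (abs(tot - (1 + fv[s])) > 1e-8)
      stop("internal consistency error: sum L^2 d = ", tot,
           " but 1 + F_s = ", 1 + fv[s])
  }
  list(owner = s, index = row$index, coef = row$coef)
}

.new_f_result <- function(ped, f, d, algorithm, diagnostics = list(), workers = 1L) {
  structure(list(f = f, d = d, algorithm = algorithm,
                 diagnostics = diagnostics, workers = as.integer(workers),
                 n = ped$n, n_meta = ped$n_meta),
            class = "inbreeding_result")
}

#' @export
print.inbreeding_result <- function(x, ...) {
  real <- x$f[seq_len(x$n) > x$n_meta]
  cat("Inbreeding coefficients (", x$algorithm, ", ", x$n, " animals, ",
      x$workers, " worker(s))\n", sep = "")
  cat("  mean F (real animals):", format(mean(real), digits = 6),
      " max F:", format(max(real), digits = 6), "\n")
  if (length(x$diagnostics))
    cat("  diagnostics:",
        paste(names(x$diagnostics), unlist(x$diagnostics), sep = "=",
              collapse = ", "), "\n")
  invisible(x)
}

#' Inbreeding coefficients, Meuwissen-Luo algorithm
#'
#' Per-animal ancestor traversal in descending identification order; the
#' elements of L are held only temporarily.  Metafounders are reported with
#' `F = gamma - 1`.
#'
#' @param ped a built `pedigree`.
#' @return An `inbreeding_result` (fields `f`, `d`, `diagnostics`).
#' @export
inbreeding_ML <- function(ped) {
  .check_ped(ped)
  r <- cpp_inbreeding_ML(ped$sire, ped$dam, ped$is_meta, ped$gamma)
  .new_f_result(ped, r$f, r$d, "ML",
                list(l_row_entries = r$l_row_entries))
}

#' Inbreeding coefficients, Sargolzaei-Iwaisaki algorithm
#'
#' Identical contract to [inbreeding_ML()] but each animal's ancestor
#' traversal pops animals in descending LAP order via per-LAP buckets (the
#' traversal shared with [L_row()]).
#'
#' @param ped a built `pedigree`.
#' @return An `inbreeding_result`.
#' @export
inbreeding_SI <- function(ped) {
  .check_ped(ped)
  r <- cpp_inbreeding_SI(ped$sire, ped$dam, ped$lap, ped$is_meta, ped$gamma)
  .new_f_result(ped, r$f, r$d, "SI",
                list(l_row_entries = r$l_row_entries))
}

#' Inbreeding coefficients, memoized recursive kinship (REC)
#'
#' F from the recursive oracle `A_ii - 1` with all computed pair
#' coefficients stored for reuse.  Subject to the oracle size cap.
#'
#' @param ped a built `pedigree`.
#' @param cap size guard as in [tabular_A()].
#' @return An `inbreeding_result`.
#' @export
inbreeding_REC <- function(ped, cap = .oracle_cap()) {
  .check_ped(ped)
  if (ped$n > cap)
    stop("pedigree size ", ped$n, " exceeds the oracle cap (", cap, ")")
  r <- cpp_rec_F(ped$sire, ped$dam, ped$is_meta, ped$gamma)
  .new_f_result(ped, r$f, d_vector(ped, r$f), "REC",
                list(pairs_stored = r$pairs_stored))
}

#' Inbreeding coefficients, tabular oracle
#'
#' F as the diagonal of the dense tabular A minus 1.  Subject to the oracle
#' size cap.
#'
#' @inheritParams inbreeding_REC
#' @return An `inbreeding_result`.
#' @export
inbreeding_tabular <- function(ped, cap = .oracle_cap()) {
  A <- tabular_A(ped, cap)
  f <- unname(diag(A) - 1)
  .new_f_result(ped, f, d_vector(ped, f), "tabular", list())
}

#' Compute inbreeding coefficients
#'
#' Front door dispatching to the six algorithms.  All methods agree to
#' within 1e-10; they differ only in cost profile.
#'
#' @param ped a built `pedigree` (see [prepare_pedigree()]).
#' @param method one of `"MI"` (modified indirect; default), `"I"`
#'   (indirect), `"SI"`, `"ML"`, `"REC"`, `"tabular"`.
#' @param workers worker count for the LAP-block parallel loop (MI only).
#' @return An `inbreeding_result`.
#' @export
inbreeding <- function(ped, method = c("MI", "I", "SI", "ML", "REC", "tabular"),
                       workers = 1L) {
  method <- match.arg(method)
  switch(method,
         MI = inbreeding_MI(ped, workers = workers),
         I = inbreeding_I(ped),
         SI = inbreeding_SI(ped),
         ML = inbreeding_ML(ped),
         REC = inbreeding_REC(ped),
         tabular = inbreeding_tabular(ped))
}
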