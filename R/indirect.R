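## indirect: the original indirect method (I) and the modified indirect
## method (MI).
##
## Both compute, per sire s, the vector y = A x with x the unit vector at s,
## by one backward and one forward triangular solve against L^-1; the F of
## each progeny j of s is then y_{d_j} / 2.  The I method performs the solves
## over a reduced pedigree (sires, mates, all their ancestors) with dense
## loops bounded by the sire's and mip_s's positions.  The MI method obtains
## z = L's,: directly from one sparse L-row and replaces the dense forward
## loop by a flagged recursion over the ancestors of the sire's mates, with
## sparse workspace reset, which makes the cost independent of pedigree size.
##
## The heavy lifting lives in compiled code; this file also carries a plain-R
## reference of the MI group evaluation (sire_workspace / evaluate_sire_group
## / y_recurse / reset_workspace) used as an independent route in the tests.

#' Reduced pedigree for the indirect method
#'
#' Extracts the transitive closure of the evaluated sires, their mates (dams
#' of their progeny) and all ancestors of both, renumbered preserving the
#' sorted (topological) order.  For each sire, `mip` records the mate with
#' the largest identification number in the reduced pedigree.
#'
#' @param ped a built `pedigree`.
#' @param sires indices (sorted order) of the sires to evaluate.
#' @return `list(kept, rindex, sire, dam, mip)`: `kept` maps reduced ->
#'   original index, `rindex` original -> reduced (NA if dropped), reduced
#'   `sire`/`dam` arrays (0 = none), and `mip` named by sire index.
#' @export
build_reduced_pedigree <- function(ped, sires) {
  .check_ped(ped)
  sires <- as.integer(sires)
  if (!length(sires)) stop("at least one sire is required")
  if (any(sires < 1L | sires > ped$n)) stop("sire index out of range")
  in_set <- logical(ped$n)
  in_set[sires] <- TRUE
  prog_of_sire <- which(!ped$is_meta & in_set[pmax(ped$sire, 1L)] & ped$sire > 0L)
  mates <- unique(ped$dam[prog_of_sire])
  seed <- unique(c(sires, mates))
  kept <- logical(ped$n)
  kept[seed] <- TRUE
  frontier <- seed
  while (length(frontier)) {                       # ancestor closure
    par <- c(ped$sire[frontier], ped$dam[frontier])
    par <- unique(par[par > 0L])
    par <- par[!kept[par]]
    kept[par] <- TRUE
    frontier <- par
  }
  kept_idx <- which(kept)                          # ascending = topological
  rindex <- rep(NA_integer_, ped$n)
  rindex[kept_idx] <- seq_along(kept_idx)
  rs <- ped$sire[kept_idx]; rd <- ped$dam[kept_idx]
  rsire <- ifelse(rs == 0L, 0L, rindex[pmax(rs, 1L)])
  rdam <- ifelse(rd == 0L, 0L, rindex[pmax(rd, 1L)])
  mip <- vapply(sires, function(s) {
    pj <- prog_of_sire[ped$sire[prog_of_sire] == s]
    if (!length(pj)) NA_integer_ else max(rindex[ped$dam[pj]])
  }, integer(1))
  names(mip) <- as.character(sires)
  list(kept = kept_idx, rindex = rindex,
       sire = as.integer(rsire), dam = as.integer(rdam), mip = mip)
}

#' Inbreeding coefficients, indirect method
#'
#' For every sire group (LAP block x sire), solves `A^-1 y = x` over one
#' reduced pedigree built across all sires: backward substitution computes
#' the nonzero z from the sire's reduced position down to the start (at most
#' two -0.5 links per row), the forward substitution `y_i = (y_si + y_di)/2
#' + d_i z_i` runs densely for `i = 1..mip_s`, and `F_j = y_{d_j}/2`.
#' Diagnostics count every element computed.
#'
#' @param ped a built `pedigree`.
#' @return An `inbreeding_result` with diagnostics
#'   `elements_computed_forward`, `elements_computed_backward`,
#'   `sire_groups` and `reduced_n`.
#' @export
inbreeding_I <- function(ped) {
  .check_ped(ped)
  r <- cpp_inbreeding_I(ped$sire, ped$dam, ped$lap, ped$is_meta, ped$gamma)
  .new_f_result(ped, r$f, r$d, "I",
                list(elements_computed_forward = r$elements_computed_forward,
                     elements_computed_backward = r$elements_computed_backward,
                     sire_groups = r$sire_groups,
                     reduced_n = r$reduced_n))
}

#' Inbreeding coefficients, modified indirect method
#'
#' Ascending-LAP outer loop; within each LAP block, progeny are grouped by
#' sire and the groups are partitioned across `workers` in contiguous
#' chunks, each worker owning a private workspace.  Per group: one sparse
#' L-row of the sire seeds `y = d * L` over the sire's ancestors
#' (metafounder seeds are final and flagged), a flagged recursion evaluates
#' `y` at each mate, `F_j = y_{d_j}/2`, and the workspace is reset sparsely
#' through the touched list.  The result is identical for any worker
#' count.
#'
#' @param ped a built `pedigree`.
#' @param workers positive worker count for the within-block parallel loop.
#' @param capture_y debug mode (forces one worker): also return every
#'   flagged `y` value as a data frame `(sire, animal, y)`; each equals the
#'   relationship `A_{animal,sire}`.
#' @return An `inbreeding_result` with diagnostics
#'   `elements_computed_forward`, `l_row_entries` and `sire_groups`; with
#'   `capture_y = TRUE` also a `capture` element.
#' @export
inbreeding_MI <- function(ped, workers = 1L, capture_y = FALSE) {
  .check_ped(ped)
  workers <- as.integer(workers)
  if (is.na(workers) || workers < 1L) stop("workers must be a positive integer")
  r <- cpp_inbreeding_MI(ped$sire, ped$dam, ped$lap, ped$is_meta, ped$gamma,
                         workers, isTRUE(capture_y))
  res <- .new_f_result(ped, r$f, r$d, "MI",
                       list(elements_computed_forward = r$elements_computed_forward,
                            l_row_entries = r$l_row_entries,
                            sire_groups = r$sire_groups),
                       workers = workers)
  if (isTRUE(capture_y)) res$capture <- r$capture
  res
}

## ---------------------------------------------------------------------------
## Plain-R reference of the MI sire-group evaluation.  Used in tests as the
## independent route against the compiled path; small pedigrees only.

#' Create a sire workspace
#'
#' Vectors `y` (numeric, all zero) and `flag` (logical, all false) of length
#' `n`, plus the list of touched indices.  Outside an evaluation the arrays
#' are all-zero/all-false (sparse reset contract); during an evaluation,
#' `flag[i]` implies `y[i] = A_{i,s}` for the owning sire `s`.
#'
#' @param ped a built `pedigree` (or an integer length).
#' @return An environment of class `sire_workspace`.
#' @export
sire_workspace <- function(ped) {
  n <- if (inherits(ped, "pedigree")) ped$n else as.integer(ped)
  ws <- new.env(parent = emptyenv())
  ws$y <- numeric(n)
  ws$flag <- logical(n)
  ws$touched <- integer(0)
  ws$owner_sire <- NA_integer_
  class(ws) <- "sire_workspace"
  ws
}

#' Flagged recursive forward substitution for one animal
#'
#' Returns `y[i] = A_{i,s}` for the workspace's current sire `s`, computing
#' each needed ancestor exactly once: if `flag[i]` the stored value is
#' returned, otherwise `y_i = (y_si + y_di)/2 + d_i z_i` where the seed term
#' `d_i L_{s,i}` already sits in `y[i]` (zero for `i` outside `ANC_s`).
#' Realized with an explicit stack, so recursion depth is unbounded.
#'
#' @param ped a built `pedigree`.
#' @param i animal index (sorted order).
#' @param d Mendelian-variance vector (unused directly: seeds already carry
#'   `d * L`; kept for contract symmetry).
#' @param ws a seeded [sire_workspace()].
#' @return `y[i]`.
#' @export
y_recurse <- function(ped, i, d, ws) {
  stack <- i
  while (length(stack)) {
    k <- stack[length(stack)]
    if (ws$flag[k]) { stack <- stack[-length(stack)]; next }
    if (ped$is_meta[k]) {        # base case: seed (or 0) is final
      ws$flag[k] <- TRUE
      ws$touched <- c(ws$touched, k)
      stack <- stack[-length(stack)]
      next
    }
    p1 <- ped$sire[k]; p2 <- ped$dam[k]
    if (ws$flag[p1] && ws$flag[p2]) {
      ws$y[k] <- ws$y[k] + 0.5 * (ws$y[p1] + ws$y[p2])
      ws$flag[k] <- TRUE
      ws$touched <- c(ws$touched, k)
      stack <- stack[-length(stack)]
    } else {
      if (!ws$flag[p1]) stack <- c(stack, p1)
      if (!ws$flag[p2] && p2 != p1) stack <- c(stack, p2)
    }
  }
  ws$y[i]
}

#' Evaluate one sire group (reference implementation)
#'
#' Computes the sparse L-row of `s`, seeds the workspace with `y = d * L`
#' over `ANC_s` (metafounders flagged at seed time), evaluates `y` at each
#' progeny's dam via [y_recurse()] and returns `F_j = y_{d_j}/2`; finally
#' resets the workspace sparsely.
#'
#' @param ped a built `pedigree`.
#' @param s the sire index.
#' @param progeny indices of the progeny of `s` to evaluate.
#' @param f finalized inbreeding coefficients for all animals of lower LAP
#'   blocks (NA allowed elsewhere).
#' @param d Mendelian-variance vector matching `f`.
#' @param ws a clean [sire_workspace()].
#' @param reset reset the workspace afterwards (default) or leave it for
#'   inspection.
#' @return Named numeric vector of F values, one per progeny.
#' @export
evaluate_sire_group <- function(ped, s, progeny, f, d, ws, reset = TRUE) {
  .check_ped(ped)
  if (any(ped$sire[progeny] != s)) stop("not all progeny belong to sire ", s)
  row <- L_row(ped, s)
  if (anyNA(f[row$index]))
    stop("precondition violated: unfinalized F among the ancestors of ", s)
  ws$owner_sire <- s
  ws$y[row$index] <- d[row$index] * row$coef
  ws$touched <- c(ws$touched, row$index)
  mf <- row$index[ped$is_meta[row$index]]
  ws$flag[mf] <- TRUE
  fj <- vapply(progeny, function(j) 0.5 * y_recurse(ped, ped$dam[j], d, ws),
               numeric(1))
  names(fj) <- as.character(progeny)
  if (reset) reset_workspace(ws)
  fj
}

#' Sparse workspace reset
#'
#' Zeroes `y` and clears `flag` only at the touched indices; cost is
#' proportional to the touched count, not the pedigree size.
#'
#' @param ws a [sire_workspace()].
#' @export
reset_workspace <- function(ws) {
  ws$y[ws$touched] <- 0
  ws$flag[ws$touched] <- FALSE
  ws$touched <- integer(0)
  ws$owner_sire <- NA_integer_
  invisible(ws)
}

#' Inbreeding via the reference R implementation of MI
#'
#' Drives [evaluate_sire_group()] over ascending LAP blocks with a single
#' workspace.  Slow; intended as an independent route for validating the
#' compiled MI path on small pedigrees.
#'
#' @param ped a built `pedigree`.
#' @return An `inbreeding_result` (algorithm tag `"MI-R"`).
#' @export
inbreeding_MI_reference <- function(ped) {
  .check_ped(ped)
  f <- rep(NA_real_, ped$n)
  d <- rep(NA_real_, ped$n)
  f[ped$is_meta] <- ped$gamma[ped$is_meta] - 1
  d[ped$is_meta] <- ped$gamma[ped$is_meta]
  ws <- sire_workspace(ped)
  blocks <- ped$lap_blocks
  for (b in seq_len(nrow(blocks))) {
    idx <- seq.int(blocks$start[b], blocks$end[b])
    idx <- idx[!ped$is_meta[idx]]
    if (!length(idx)) next
    fb <- rep(NA_real_, length(idx))
    for (s in unique(ped$sire[idx])) {
      prog <- idx[ped$sire[idx] == s]
      fb[match(prog, idx)] <- evaluate_sire_group(ped, s, prog, f, d, ws)
    }
    f[idx] <- fb
    d[idx] <- mendelian_variance(f[ped$sire[idx]], f[ped$dam[idx]])
  }
  .new_f_result(ped, f, d, "MI-R")
}
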