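# Shared fixtures and independent oracles, all built in code.

# Five real animals: founders 1,2; full sibs 3,4; inbred child 5 (F = 0.25).
toy_fullsib_raw <- function() {
  raw_pedigree(as.character(1:5),
               c(NA, NA, "1", "1", "3"),
               c(NA, NA, "2", "2", "4"))
}

toy_fullsib_ped <- function(gamma = 0) {
  build_pedigree(assign_metafounders(
    toy_fullsib_raw(), metafounder_policy(gamma_default = gamma)))
}

# Repeated full-sib line: a0 x b0 -> a1, b1 (full sibs) -> a2, b2 -> ...
# F of generation-(t+1) animals follows Wright's recurrence
# F_t = 0.25 (1 + 2 F_{t-1} + F_{t-2}), F_1 = 0.25.
fullsib_line_raw <- function(generations) {
  id <- c("a0", "b0"); s <- c(NA, NA); d <- c(NA, NA)
  for (t in seq_len(generations)) {
    id <- c(id, paste0(c("a", "b"), t))
    s <- c(s, rep(paste0("a", t - 1), 2))
    d <- c(d, rep(paste0("b", t - 1), 2))
  }
  raw_pedigree(id, s, d)
}

wright_F <- function(tmax) {
  f <- numeric(tmax + 2)          # f[t + 2] = F_t, F_0 = F_{-1} = 0
  for (t in seq_len(tmax)) f[t + 2] <- 0.25 * (1 + 2 * f[t + 1] + f[t])
  f[seq_len(tmax) + 2]
}

# Random layered pedigree with inbreeding loops and unknown parents.
# Layer-0 animals always have unknown parents; other slots are unknown with
# probability p_unknown.  Years = 1900 + layer, so year-bin metafounders get
# one bin per layer.
random_raw_pedigree <- function(n, depth = 10, p_unknown = 0.3, seed = 1) {
  set.seed(seed)
  layer <- sort(sample(0:depth, n, replace = TRUE))
  layer[1] <- 0L
  counts <- tabulate(layer + 1L, nbins = depth + 1L)
  nlow <- c(0L, cumsum(counts))[layer + 1L]   # animals in strictly lower layers
  id <- paste0("A", seq_len(n))
  draw <- function() {
    idx <- ceiling(runif(n) * pmax(nlow, 1L))
    out <- id[idx]
    out[nlow == 0L | runif(n) < p_unknown] <- NA_character_
    out
  }
  raw_pedigree(id, draw(), draw(), year = 1900L + layer)
}

random_ped <- function(n, depth = 10, p_unknown = 0.3, seed = 1, gamma = 0) {
  build_pedigree(assign_metafounders(
    random_raw_pedigree(n, depth, p_unknown, seed),
    metafounder_policy(gamma_default = gamma)))
}

# Independent classical oracle: plain-R tabular method over raw records,
# treating every unknown parent slot as its own unrelated founder (F = 0 at
# the base).  Returns F named by animal id.  O(n^2); tiny pedigrees only.
classical_tabular_F <- function(raw) {
  n <- length(raw$id)
  si <- match(raw$sire, raw$id)
  di <- match(raw$dam, raw$id)
  # topological order by repeated sweeps
  done <- logical(n); ord <- integer(0)
  while (length(ord) < n) {
    ready <- which(!done & (is.na(si) | done[si]) & (is.na(di) | done[di]))
    stopifnot(length(ready) > 0)
    done[ready] <- TRUE
    ord <- c(ord, ready)
  }
  pos <- integer(n); pos[ord] <- seq_len(n)
  A <- matrix(0, n, n)
  for (k in seq_len(n)) {
    i <- ord[k]
    s <- si[i]; d <- di[i]
    rs <- if (is.na(s)) NULL else pos[s]
    rd <- if (is.na(d)) NULL else pos[d]
    for (m in seq_len(k - 1L)) {
      v <- 0.5 * ((if (is.null(rs)) 0 else A[rs, m]) +
                  (if (is.null(rd)) 0 else A[rd, m]))
      A[k, m] <- v; A[m, k] <- v
    }
    A[k, k] <- 1 + 0.5 * (if (is.null(rs) || is.null(rd)) 0 else A[rs, rd])
  }
  f <- diag(A) - 1
  names(f) <- raw$id[ord]
  f[raw$id]
}

# F vector of the real animals of a built pedigree, named by original id.
real_F <- function(ped, res) {
  f <- if (inherits(res, "inbreeding_result")) res$f else res
  out <- f[!ped$is_meta]
  names(out) <- ped$orig_id[!ped$is_meta]
  out
}
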