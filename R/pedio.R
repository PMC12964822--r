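## pedio: reading, validating, cleaning, metafounder assignment, LAP sorting
## and result output.
##
## A raw pedigree is a set of records (animal, sire, dam, birth year) keyed by
## character identifiers; unknown parents are NA internally.  A built pedigree
## is renumbered 1..n, sorted by ascending LAP (longest ancestral path) so
## that parents strictly precede progeny and metafounders lead the array.

#' Construct a raw pedigree
#'
#' @param id character vector of animal identifiers (unique).
#' @param sire,dam character vectors of parent identifiers; `NA` = unknown.
#' @param year integer vector of birth years (`NA` = missing) or `NULL`.
#' @param is_meta logical vector flagging metafounder records; default all
#'   `FALSE`.
#' @param gamma numeric vector of metafounder self-relationships in `[0, 1)`;
#'   ignored for real animals.
#' @return An object of class `raw_pedigree`.
#' @export
raw_pedigree <- function(id, sire, dam, year = NULL, is_meta = NULL, gamma = NULL) {
  id <- as.character(id); sire <- as.character(sire); dam <- as.character(dam)
  n <- length(id)
  stopifnot(length(sire) == n, length(dam) == n)
  if (is.null(year)) year <- rep(NA_integer_, n)
  year <- as.integer(year)
  if (is.null(is_meta)) is_meta <- rep(FALSE, n)
  if (is.null(gamma)) gamma <- rep(0, n)
  dup <- anyDuplicated(id)
  if (dup) stop("duplicate animal identifier: '", id[dup], "'")
  self <- which(!is.na(sire) & sire == id | !is.na(dam) & dam == id)
  if (length(self))
    stop("animal '", id[self[1]], "' is recorded as its own parent")
  if (any(gamma < 0 | gamma >= 1))
    stop("metafounder gamma values must lie in [0, 1)")
  structure(list(id = id, sire = sire, dam = dam, year = year,
                 is_meta = is_meta, gamma = gamma),
            class = "raw_pedigree")
}

#' @export
print.raw_pedigree <- function(x, ...) {
  cat("Raw pedigree:", length(x$id), "records (",
      sum(x$is_meta), "metafounders,",
      sum(is.na(x$sire) | is.na(x$dam)), "records with unknown parents )\n")
  invisible(x)
}

#' @export
length.raw_pedigree <- function(x) length(x$id)

#' Read a delimited pedigree file
#'
#' One record per line: animal id, sire id, dam id and optionally a birth
#' year.  The delimiter is auto-detected (tab, comma, then whitespace) unless
#' given.  Parents that are referenced but never appear as records are
#' appended as founder records with unknown parents ("padding").
#'
#' @param path path to the pedigree file.
#' @param sep field delimiter; `NULL` to auto-detect.  `"white"` means any
#'   run of blanks/tabs.
#' @param unknown tokens denoting an unknown parent (besides the empty
#'   string).
#' @param pad_parents append records for parents that are referenced but not
#'   listed?
#' @return A [raw_pedigree()]; attribute `n_padded` counts appended parents.
#' @export
read_pedigree <- function(path, sep = NULL, unknown = c("0", "NA", "."),
                          pad_parents = TRUE) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]; lineno <- lineno[keep]
  if (!length(lines))
    return(raw_pedigree(character(), character(), character()))
  if (is.null(sep)) {
    probe <- lines[1]
    sep <- if (grepl("\t", probe)) "\t" else if (grepl(",", probe)) "," else "white"
  }
  split <- if (identical(sep, "white")) "[ \t]+" else sep
  fixed <- !identical(sep, "white")
  cols <- data.table::tstrsplit(trimws(lines), split, fixed = fixed, fill = NA_character_)
  if (length(cols) < 3) {
    bad <- which(is.na(data.table::tstrsplit(trimws(lines), split, fixed = fixed,
                                             fill = NA_character_)[[min(length(cols) + 1L, 3L)]]))
    stop("line ", lineno[if (length(bad)) bad[1] else 1],
         ": expected at least 3 fields (animal, sire, dam)")
  }
  if (length(cols) > 4)
    stop("line ", lineno[which(!is.na(cols[[5]]))[1]],
         ": expected at most 4 fields (animal, sire, dam, birth year)")
  miss <- which(is.na(cols[[2]]) | is.na(cols[[3]]))
  if (length(miss))
    stop("line ", lineno[miss[1]], ": expected at least 3 fields (animal, sire, dam)")
  id <- cols[[1]]; sire <- cols[[2]]; dam <- cols[[3]]
  year <- rep(NA_integer_, length(id))
  if (length(cols) == 4) {
    ytxt <- cols[[4]]
    y <- suppressWarnings(as.integer(ytxt))
    bad <- which(!is.na(ytxt) & nzchar(ytxt) & is.na(y))
    if (length(bad))
      stop("line ", lineno[bad[1]], ": birth year '", ytxt[bad[1]], "' is not an integer")
    year <- y
  }
  unk <- function(x) { x[is.na(x) | x %in% unknown | !nzchar(x)] <- NA_character_; x }
  sire <- unk(sire); dam <- unk(dam)
  n_padded <- 0L
  if (pad_parents) {
    missing_par <- setdiff(stats::na.omit(unique(c(sire, dam))), id)
    if (length(missing_par)) {
      n_padded <- length(missing_par)
      id <- c(id, missing_par)
      sire <- c(sire, rep(NA_character_, n_padded))
      dam <- c(dam, rep(NA_character_, n_padded))
      year <- c(year, rep(NA_integer_, n_padded))
    }
  }
  out <- raw_pedigree(id, sire, dam, year)
  attr(out, "n_padded") <- n_padded
  out
}

#' Write a raw pedigree to a delimited text file
#'
#' Inverse of [read_pedigree()]: columns animal, sire, dam, birth year, with
#' `0` for unknown parents and an empty field for a missing year.
#'
#' @param ped a [raw_pedigree()].
#' @param path output path.
#' @param sep field delimiter (default tab).
#' @export
write_pedigree <- function(ped, path, sep = "\t") {
  stopifnot(inherits(ped, "raw_pedigree"))
  enc <- function(x) { x[is.na(x)] <- "0"; x }
  df <- data.table::data.table(
    animal = ped$id, sire = enc(ped$sire), dam = enc(ped$dam),
    year = ifelse(is.na(ped$year), "", as.character(ped$year)))
  data.table::fwrite(df, path, sep = sep, col.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Impute missing birth years from progeny
#'
#' An animal with a missing birth year and at least one dated (or
#' recursively datable) progeny receives the birth year of its oldest
#' progeny minus `interval` years (a plausible generation interval).
#' Resolution proceeds in reverse topological order, realized as a fixpoint
#' so that chains of missing years resolve from descendants upwards; animals
#' with no dated descendants remain missing.
#'
#' @param ped a [raw_pedigree()].
#' @param interval generation-interval offset in years (default 3).
#' @return `list(pedigree = <raw_pedigree>, n_imputed = <integer>)`.
#' @export
impute_birth_years <- function(ped, interval = 3L) {
  stopifnot(inherits(ped, "raw_pedigree"))
  n <- length(ped$id)
  year <- ped$year
  orig_missing <- is.na(year) & !ped$is_meta
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  pidx <- c(si, di)
  cidx <- rep(seq_len(n), 2L)
  ok_link <- !is.na(pidx)
  pidx <- pidx[ok_link]; cidx <- cidx[ok_link]
  for (pass in seq_len(n + 1L)) {
    cy <- year[cidx]
    has <- !is.na(cy)
    if (!any(has)) break
    m <- tapply(cy[has], pidx[has], min)
    cand <- rep(NA_integer_, n)
    cand[as.integer(names(m))] <- as.integer(m) - as.integer(interval)
    upd <- orig_missing & !is.na(cand) & (is.na(year) | year != cand)
    if (!any(upd)) break
    year[upd] <- cand[upd]
  }
  n_imputed <- sum(orig_missing & !is.na(year))
  ped$year <- year
  list(pedigree = ped, n_imputed = as.integer(n_imputed))
}

#' Sever parent links that violate birth order
#'
#' Any parent recorded as born in the same year as, or later than, its
#' progeny is set to unknown.  Links are counted individually.  The
#' operation is idempotent.
#'
#' @param ped a [raw_pedigree()] with years resolved where possible.
#' @return `list(pedigree = <raw_pedigree>, n_fixed = <integer>)`.
#' @export
fix_birth_order_errors <- function(ped) {
  stopifnot(inherits(ped, "raw_pedigree"))
  year <- ped$year
  bad_link <- function(parent) {
    pi <- match(parent, ped$id)
    !is.na(pi) & !is.na(year[pi]) & !is.na(year) & year[pi] >= year
  }
  bs <- bad_link(ped$sire)
  bd <- bad_link(ped$dam)
  ped$sire[bs] <- NA_character_
  ped$dam[bd] <- NA_character_
  list(pedigree = ped, n_fixed = as.integer(sum(bs) + sum(bd)))
}

#' Metafounder policy
#'
#' Unknown parents are replaced by metafounders, one per occupied birth-year
#' bin of the progeny (optionally one per bin and parental role).  A
#' metafounder's self-relationship is gamma (`A_mm = gamma`, `F_m = gamma -
#' 1`); `gamma = 0` reproduces the classical unrelated-founder model
#' exactly.
#'
#' @param bin_width_years width of the year bins (positive integer).
#' @param gamma_default self-relationship used for every bin without an
#'   entry in `per_bin_gamma`; in `[0, 1)`.
#' @param per_bin_gamma optional named numeric vector, names = bin start
#'   years.
#' @param sex_split create separate sire- and dam-metafounders per bin?
#' @return An object of class `metafounder_policy`.
#' @export
metafounder_policy <- function(bin_width_years = 1L, gamma_default = 0,
                               per_bin_gamma = NULL, sex_split = FALSE) {
  stopifnot(bin_width_years >= 1, gamma_default >= 0, gamma_default < 1)
  if (!is.null(per_bin_gamma) &&
      (any(per_bin_gamma < 0) || any(per_bin_gamma >= 1)))
    stop("per-bin gamma values must lie in [0, 1)")
  structure(list(bin_width_years = as.integer(bin_width_years),
                 gamma_default = gamma_default,
                 per_bin_gamma = per_bin_gamma,
                 sex_split = isTRUE(sex_split)),
            class = "metafounder_policy")
}

#' Assign unknown parents to metafounders
#'
#' Creates one metafounder per occupied birth-year bin (serving both
#' parental roles unless the policy splits by sex), fills every unknown
#' parent slot with the metafounder of the progeny's bin, and prepends the
#' metafounder records.  Undated progeny fall back to the earliest bin.
#'
#' @param ped a [raw_pedigree()] whose birth-order errors are fixed.
#' @param policy a [metafounder_policy()].
#' @return A [raw_pedigree()] with metafounders prepended; attribute
#'   `n_metafounders` gives the number added.
#' @export
assign_metafounders <- function(ped, policy = metafounder_policy()) {
  stopifnot(inherits(ped, "raw_pedigree"), inherits(policy, "metafounder_policy"))
  if (any(ped$is_meta)) stop("pedigree already contains metafounders")
  need_s <- is.na(ped$sire)
  need_d <- is.na(ped$dam)
  if (!any(need_s | need_d)) {
    attr(ped, "n_metafounders") <- 0L
    return(ped)
  }
  yrs <- ped$year
  have_years <- any(!is.na(yrs))
  base <- if (have_years) min(yrs, na.rm = TRUE) else 0L
  bw <- policy$bin_width_years
  bin_of <- function(y) ifelse(is.na(y), 0L, (y - base) %/% bw)  # fallback: earliest bin
  bins_needed <- sort(unique(bin_of(yrs[need_s | need_d])))
  bin_start <- base + bins_needed * bw
  mk_id <- function(start, role) {
    lab <- if (have_years) as.character(start) else rep("U", length(start))
    if (policy$sex_split) paste0("<MF:", lab, ":", role, ">") else paste0("<MF:", lab, ">")
  }
  gamma_of <- function(start) {
    key <- as.character(start)
    if (!is.null(policy$per_bin_gamma) && key %in% names(policy$per_bin_gamma))
      unname(policy$per_bin_gamma[key]) else policy$gamma_default
  }
  roles <- if (policy$sex_split) c("S", "D") else "X"
  mf_bin_start <- rep(bin_start, each = length(roles))   # bin-major, role within
  mf_role <- rep(roles, times = length(bin_start))
  mf_id <- mapply(mk_id, mf_bin_start, mf_role, USE.NAMES = FALSE)
  clash <- intersect(mf_id, ped$id)
  if (length(clash))
    stop("metafounder identifier clashes with an existing animal id: ", clash[1])
  mf_gamma <- vapply(mf_bin_start, gamma_of, numeric(1))
  lookup <- function(role) mk_id(base + bin_of(yrs) * bw, role)
  sire <- ped$sire; dam <- ped$dam
  sire[need_s] <- lookup(if (policy$sex_split) "S" else "X")[need_s]
  dam[need_d]  <- lookup(if (policy$sex_split) "D" else "X")[need_d]
  out <- raw_pedigree(
    id = c(mf_id, ped$id),
    sire = c(rep(NA_character_, length(mf_id)), sire),
    dam = c(rep(NA_character_, length(mf_id)), dam),
    year = c(rep(NA_integer_, length(mf_id)), ped$year),
    is_meta = c(rep(TRUE, length(mf_id)), rep(FALSE, length(ped$id))),
    gamma = c(mf_gamma, rep(0, length(ped$id))))
  attr(out, "n_metafounders") <- length(mf_id)
  out
}

#' Build a renumbered, LAP-sorted pedigree
#'
#' Computes the longest ancestral path LAP_i (0 for metafounders,
#' `max(LAP_sire, LAP_dam) + 1` for real animals), sorts records stably by
#' ascending LAP (original order breaks ties), renumbers 1..n and records
#' the boundaries of equal-LAP blocks.  Every real animal must have both
#' parents present -- run [assign_metafounders()] first.
#'
#' @param ped a [raw_pedigree()] in which every unknown parent slot has been
#'   filled by a metafounder.
#' @return An object of class `pedigree` with fields `n`, `n_meta`, `sire`,
#'   `dam` (1-based indices, 0 = none), `lap`, `is_meta`, `gamma`,
#'   `orig_id`, `raw_pos` and `lap_blocks`.
#' @export
build_pedigree <- function(ped) {
  stopifnot(inherits(ped, "raw_pedigree"))
  n <- length(ped$id)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  real <- !ped$is_meta
  bad <- which(real & (!is.na(ped$sire) & is.na(si) | !is.na(ped$dam) & is.na(di)))
  if (length(bad))
    stop("animal '", ped$id[bad[1]], "' references a parent with no record")
  bad <- which(real & (is.na(si) | is.na(di)))
  if (length(bad))
    stop("real animal '", ped$id[bad[1]],
         "' has an unknown parent; run assign_metafounders() first")
  si0 <- ifelse(is.na(si), 0L, si)
  di0 <- ifelse(is.na(di), 0L, di)
  lap <- cpp_lap(si0, di0, ped$is_meta)
  ord <- order(lap, seq_len(n))           # stable: original order breaks ties
  pos <- integer(n); pos[ord] <- seq_len(n)
  sire_new <- ifelse(si0[ord] == 0L, 0L, pos[pmax(si0[ord], 1L)])
  dam_new  <- ifelse(di0[ord] == 0L, 0L, pos[pmax(di0[ord], 1L)])
  lap_s <- lap[ord]
  blocks <- data.frame(
    lap = unique(lap_s),
    start = match(unique(lap_s), lap_s),
    end = n + 1L - match(unique(lap_s), rev(lap_s)))
  structure(list(
    n = n,
    n_meta = sum(ped$is_meta),
    sire = as.integer(sire_new),
    dam = as.integer(dam_new),
    lap = as.integer(lap_s),
    is_meta = ped$is_meta[ord],
    gamma = ped$gamma[ord],
    orig_id = ped$id[ord],
    year = ped$year[ord],
    raw_pos = ord,
    lap_blocks = blocks), class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  lr <- x$lap[!x$is_meta]
  cat("LAP-sorted pedigree: n =", x$n, "(", x$n_meta, "metafounders )\n")
  if (length(lr))
    cat("LAP of real animals: max", max(lr), ", mean", round(mean(lr), 2),
        ", median", median(lr), "\n")
  invisible(x)
}

#' Turn a pedigree back into raw records (in sorted order)
#' @param ped a `pedigree`.
#' @return A [raw_pedigree()].
#' @export
as_raw_pedigree <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  idx2id <- function(i) ifelse(i == 0L, NA_character_, ped$orig_id[i])
  raw_pedigree(ped$orig_id, idx2id(ped$sire), idx2id(ped$dam), ped$year,
               is_meta = ped$is_meta, gamma = ped$gamma)
}

#' Clean and build a pedigree in one call
#'
#' Applies the full cleaning pipeline in fixed order: impute missing birth
#' years (oldest progeny minus `interval`), sever parents born no earlier
#' than their progeny, assign metafounders per birth-year bin, build and
#' LAP-sort.
#'
#' @inheritParams impute_birth_years
#' @param policy a [metafounder_policy()].
#' @return `list(pedigree, n_imputed, n_fixed, n_metafounders)`.
#' @export
prepare_pedigree <- function(ped, interval = 3L, policy = metafounder_policy()) {
  imp <- impute_birth_years(ped, interval)
  fix <- fix_birth_order_errors(imp$pedigree)
  aug <- assign_metafounders(fix$pedigree, policy)
  list(pedigree = build_pedigree(aug),
       n_imputed = imp$n_imputed,
       n_fixed = fix$n_fixed,
       n_metafounders = attr(aug, "n_metafounders"))
}

#' Write inbreeding results
#'
#' Tab-separated columns `original_id`, `F`, `LAP`, ordered as in the
#' original input.  Metafounders (F = gamma - 1) are excluded unless
#' requested, in which case they come first.
#'
#' @param ped the `pedigree` the result was computed on.
#' @param f an inbreeding result (see [inbreeding()]) or a numeric vector of
#'   length `ped$n` in sorted order.
#' @param path output path.
#' @param include_metafounders include metafounder rows first?
#' @export
write_results <- function(ped, f, path, include_metafounders = FALSE) {
  stopifnot(inherits(ped, "pedigree"))
  fv <- if (inherits(f, "inbreeding_result")) f$f else f
  if (length(fv) != ped$n) stop("F vector length does not match the pedigree")
  idx_meta <- which(ped$is_meta)
  idx_real <- which(!ped$is_meta)
  idx_real <- idx_real[order(ped$raw_pos[idx_real])]   # original input order
  idx <- if (include_metafounders) c(idx_meta, idx_real) else idx_real
  df <- data.table::data.table(original_id = ped$orig_id[idx],
                               F = fv[idx],
                               LAP = ped$lap[idx])
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(NULL)
}
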