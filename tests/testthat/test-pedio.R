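test_that("read_pedigree parses records, years and unknown tokens", {
  p <- withr::local_tempfile(lines = c("1 0 0", "2 0 0", "3 1 2"))
  raw <- read_pedigree(p)
  expect_s3_class(raw, "raw_pedigree")
  expect_length(raw, 3)
  expect_identical(raw$sire[3], "1")
  expect_identical(raw$dam[3], "2")
  expect_true(all(is.na(raw$sire[1:2])))

  p4 <- withr::local_tempfile(lines = c("1\t0\t0\t1990", "2\t1\t0\t1995"))
  raw4 <- read_pedigree(p4)
  expect_identical(raw4$year, c(1990L, 1995L))

  pc <- withr::local_tempfile(lines = c("x,0,0", "y,x,0"))
  expect_identical(read_pedigree(pc)$sire[2], "x")
})

test_that("read_pedigree rejects malformed input with line numbers", {
  p <- withr::local_tempfile(lines = c("1 0 0", "2 0"))
  expect_error(read_pedigree(p), "line 2")
  pd <- withr::local_tempfile(lines = c("1 0 0", "1 0 0"))
  expect_error(read_pedigree(pd), "duplicate")
  ps <- withr::local_tempfile(lines = c("5 5 0"))
  expect_error(read_pedigree(ps), "own parent")
  py <- withr::local_tempfile(lines = c("1 0 0 abc"))
  expect_error(read_pedigree(py), "birth year")
  expect_error(read_pedigree(file.path(tempdir(), "nope.txt")), "not found")
})

test_that("read_pedigree pads referenced-but-unlisted parents", {
  p <- withr::local_tempfile(lines = c("3 1 2"))
  raw <- read_pedigree(p)
  expect_length(raw, 3)
  expect_identical(attr(raw, "n_padded"), 2L)
  expect_setequal(raw$id, c("3", "1", "2"))
})

test_that("pedigree write/read round-trip preserves links and years", {
  raw <- random_raw_pedigree(80, depth = 6, seed = 11)
  p <- withr::local_tempfile()
  write_pedigree(raw, p)
  back <- read_pedigree(p)
  expect_identical(back$id, raw$id)
  expect_identical(back$sire, raw$sire)
  expect_identical(back$dam, raw$dam)
  expect_identical(back$year, raw$year)
})

test_that("birth-year imputation applies oldest-progeny-minus-interval", {
  # parent with oldest progeny born 1990 -> 1987
  raw <- raw_pedigree(c("p", "c1", "c2"), c(NA, "p", "p"), c(NA, NA, NA),
                      year = c(NA, 1992L, 1990L))
  out <- impute_birth_years(raw)
  expect_identical(out$pedigree$year[1], 1987L)
  expect_identical(out$n_imputed, 1L)

  # chain: only the grandchild dated -> parent 1997, grandparent 1994
  chain <- raw_pedigree(c("g", "p", "c"), c(NA, "g", "p"), c(NA, NA, NA),
                        year = c(NA, NA, 2000L))
  out2 <- impute_birth_years(chain)
  expect_identical(out2$pedigree$year, c(1994L, 1997L, 2000L))
  expect_identical(out2$n_imputed, 2L)

  # no progeny and no year: untouched, not counted
  lone <- raw_pedigree(c("x", "y"), c(NA, NA), c(NA, NA), c(NA, 1980L))
  out3 <- impute_birth_years(lone)
  expect_true(is.na(out3$pedigree$year[1]))
  expect_identical(out3$n_imputed, 0L)

  # custom interval
  expect_identical(impute_birth_years(raw, interval = 5)$pedigree$year[1], 1985L)
})

test_that("imputation resolves multi-progeny chains in reverse topological order", {
  # p has progeny c1 (dated 2000) and c2 (imputable to 1995 via its own child)
  raw <- raw_pedigree(c("p", "c1", "c2", "gc"),
                      c(NA, "p", "p", "c2"), c(NA, NA, NA, NA),
                      year = c(NA, 2000L, NA, 1998L))
  out <- impute_birth_years(raw)
  expect_identical(out$pedigree$year[3], 1995L)   # c2 = 1998 - 3
  expect_identical(out$pedigree$year[1], 1992L)   # p = min(2000, 1995) - 3
})

test_that("birth-order repair severs same-or-later-year parents, idempotently", {
  raw <- raw_pedigree(c("s", "d", "c1", "c2"),
                      c(NA, NA, "s", "s"), c(NA, NA, "d", "d"),
                      year = c(2000L, 2005L, 2000L, 2003L))
  out <- fix_birth_order_errors(raw)
  # c1: sire born same year -> severed; dam born later -> severed
  # c2: sire 2000 < 2003 fine; dam 2005 >= 2003 -> severed
  expect_true(is.na(out$pedigree$sire[3]))
  expect_true(is.na(out$pedigree$dam[3]))
  expect_identical(out$pedigree$sire[4], "s")
  expect_true(is.na(out$pedigree$dam[4]))
  expect_identical(out$n_fixed, 3L)
  again <- fix_birth_order_errors(out$pedigree)
  expect_identical(again$n_fixed, 0L)
  expect_identical(again$pedigree, out$pedigree)
})

test_that("metafounders are created per occupied year-bin and fill all slots", {
  raw <- raw_pedigree(c("a", "b", "c", "d"),
                      c(NA, NA, "a", NA), c(NA, NA, NA, NA),
                      year = c(1901L, 1950L, 1951L, 2023L))
  aug <- assign_metafounders(raw)
  expect_identical(attr(aug, "n_metafounders"), 4L)  # bins 1901, 1950, 1951, 2023
  expect_false(anyNA(aug$sire[!aug$is_meta]))
  expect_false(anyNA(aug$dam[!aug$is_meta]))
  # one shared metafounder when a single founder pair occupies one bin
  pair <- raw_pedigree(c("f", "m"), c(NA, NA), c(NA, NA), c(1990L, 1990L))
  expect_identical(attr(assign_metafounders(pair), "n_metafounders"), 1L)
  # no unknown parent slots anywhere: nothing to assign
  none <- raw_pedigree(character(), character(), character())
  expect_identical(attr(assign_metafounders(none), "n_metafounders"), 0L)
  # wider bins merge years
  aug2 <- assign_metafounders(raw, metafounder_policy(bin_width_years = 200L))
  expect_identical(attr(aug2, "n_metafounders"), 1L)
  # sex-split doubles the metafounders per bin
  aug3 <- assign_metafounders(pair, metafounder_policy(sex_split = TRUE))
  expect_identical(attr(aug3, "n_metafounders"), 2L)
  expect_false(identical(aug3$sire[!aug3$is_meta], aug3$dam[!aug3$is_meta]))
})

test_that("metafounder gamma policy is applied per bin", {
  raw <- raw_pedigree(c("a", "b"), c(NA, NA), c(NA, NA), c(1990L, 2000L))
  pol <- metafounder_policy(gamma_default = 0.1,
                            per_bin_gamma = c("2000" = 0.3))
  aug <- assign_metafounders(raw, pol)
  expect_identical(aug$gamma[aug$is_meta], c(0.1, 0.3))
  expect_error(metafounder_policy(gamma_default = 1), "gamma")
})

test_that("build_pedigree computes LAP, sorts stably and renumbers", {
  # chain MF -> A -> B -> C gives LAPs 0,1,2,3
  raw <- raw_pedigree(c("A", "B", "C"), c(NA, "A", "B"), c(NA, "A", "B"))
  ped <- build_pedigree(assign_metafounders(raw))
  expect_identical(ped$lap, c(0L, 1L, 2L, 3L))
  expect_identical(ped$orig_id[-1], c("A", "B", "C"))

  # LAP = max(parents) + 1: A with a metafounder sire (LAP 0) and dam B of
  # LAP 4 gets 5
  raw2 <- raw_pedigree(c("p1", "p2", "p3", "B", "A"),
                       c(NA, "p1", "p2", "p3", NA),
                       c(NA, "p1", "p2", "p3", "B"))
  ped2 <- build_pedigree(assign_metafounders(raw2))
  expect_identical(ped2$lap[ped2$orig_id == "A"], 5L)
  expect_identical(ped2$lap[ped2$orig_id == "B"], 4L)

  # invariants: parents precede progeny in index and LAP; sort is a permutation
  ped3 <- random_ped(300, seed = 3)
  real <- which(!ped3$is_meta)
  expect_true(all(ped3$sire[real] < real & ped3$dam[real] < real))
  expect_true(all(ped3$lap[ped3$sire[real]] < ped3$lap[real]))
  expect_true(all(ped3$lap[ped3$dam[real]] < ped3$lap[real]))
  expect_setequal(ped3$orig_id, assign_metafounders(
    random_raw_pedigree(300, seed = 3))$id)
  # LAP blocks tile 1..n
  expect_identical(ped3$lap_blocks$start[1], 1L)
  expect_identical(ped3$lap_blocks$end[nrow(ped3$lap_blocks)], ped3$n)
  # metafounders first
  expect_identical(which(ped3$is_meta), seq_len(ped3$n_meta))
})

test_that("build_pedigree detects cycles and dangling parents", {
  raw <- raw_pedigree(c("a", "b", "c"), c("c", "a", "b"), c("c", "a", "b"))
  expect_error(build_pedigree(raw), "cycle")
  dangle <- raw_pedigree(c("a"), c("ghost"), c("ghost"))
  expect_error(build_pedigree(dangle), "no record")
  unk <- raw_pedigree(c("a"), NA_character_, NA_character_)
  expect_error(build_pedigree(unk), "assign_metafounders")
})

test_that("write_results emits original input order with optional metafounders", {
  ped <- toy_fullsib_ped()
  res <- inbreeding(ped, "MI")
  p <- withr::local_tempfile()
  write_results(ped, res, p)
  tab <- read.delim(p)
  expect_identical(nrow(tab), 5L)
  expect_identical(tab$original_id, 1:5)          # original input order
  expect_equal(tab$F[tab$original_id == 5], 0.25)
  write_results(ped, res, p, include_metafounders = TRUE)
  tab2 <- read.delim(p, colClasses = c(original_id = "character"))
  expect_identical(nrow(tab2), 6L)
  expect_equal(tab2$F[1], -1)                      # gamma - 1 with gamma = 0
  expect_true(startsWith(tab2$original_id[1], "<MF"))
  # empty pedigree: header only
  e <- build_pedigree(raw_pedigree(character(), character(), character()))
  write_results(e, numeric(0), p)
  expect_identical(nrow(read.delim(p)), 0L)
})

test_that("gamma = 0 metafounders reproduce the classical unrelated-founder F", {
  for (seed in 1:8) {
    raw <- random_raw_pedigree(60, depth = 6, p_unknown = 0.4, seed = seed)
    ped <- build_pedigree(assign_metafounders(raw))
    f_pkg <- real_F(ped, inbreeding(ped, "tabular"))
    f_classic <- classical_tabular_F(raw)
    expect_equal(f_pkg[names(f_classic)], f_classic, tolerance = 1e-12)
  }
})
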