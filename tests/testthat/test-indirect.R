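test_that("build_reduced_pedigree keeps sires, mates and all ancestors", {
  # sire k1 (parents f1 x f2), one mate k2 (parents f3 x f4), progeny j
  raw <- raw_pedigree(c("f1", "f2", "f3", "f4", "k1", "k2", "j", "lone"),
                      c(NA, NA, NA, NA, "f1", "f3", "k1", NA),
                      c(NA, NA, NA, NA, "f2", "f4", "k2", NA))
  ped <- build_pedigree(assign_metafounders(raw))
  s <- which(ped$orig_id == "k1")
  red <- build_reduced_pedigree(ped, s)
  kept_ids <- ped$orig_id[red$kept]
  expect_setequal(setdiff(kept_ids, ped$orig_id[ped$is_meta]),
                  c("f1", "f2", "f3", "f4", "k1", "k2"))   # 6 real animals, no j, no lone
  expect_identical(unname(red$mip[as.character(s)]),
                   red$rindex[which(ped$orig_id == "k2")])
  # reduced numbering is topological
  real_red <- which(red$sire > 0L)
  expect_true(all(red$sire[real_red] < real_red & red$dam[real_red] < real_red))
  # evaluating every sire of a sire-progeny chain keeps the whole chain
  chain <- build_pedigree(assign_metafounders(fullsib_line_raw(4)))
  sires <- unique(chain$sire[!chain$is_meta])
  red2 <- build_reduced_pedigree(chain, sires)
  # everything except the final (childless) generation is kept
  expect_setequal(setdiff(chain$orig_id[red2$kept],
                          chain$orig_id[chain$is_meta]),
                  setdiff(chain$orig_id[!chain$is_meta], c("a4", "b4")))
  expect_error(build_reduced_pedigree(ped, integer(0)), "at least one")
})

test_that("indirect method matches the tabular oracle and counts elements", {
  ped <- toy_fullsib_ped()
  r <- inbreeding_I(ped)
  expect_equal(unname(real_F(ped, r)["5"]), 0.25)
  for (seed in 1:10) {
    gam <- if (seed %% 2 == 0) 0.2 else 0
    p <- random_ped(250, depth = 12, seed = seed, gamma = gam)
    expect_lt(max(abs(inbreeding_I(p)$f - inbreeding(p, "tabular")$f)), 1e-10)
  }
  # forward elements grow with reduced-pedigree size even for a single mate:
  # the Eq-style loop always runs 1..mip_s
  short <- build_pedigree(assign_metafounders(fullsib_line_raw(3)))
  long <- build_pedigree(assign_metafounders(fullsib_line_raw(12)))
  expect_gt(inbreeding_I(long)$diagnostics$elements_computed_forward /
              inbreeding_I(long)$diagnostics$sire_groups,
            inbreeding_I(short)$diagnostics$elements_computed_forward /
              inbreeding_I(short)$diagnostics$sire_groups)
})

test_that("evaluate_sire_group reproduces the hand-traced full-sib seed and F", {
  ped <- toy_fullsib_ped()
  A <- tabular_A(ped)
  f <- unname(diag(A) - 1)
  d <- d_vector(ped, f)
  s <- which(ped$orig_id == "3"); mate <- which(ped$orig_id == "4")
  j <- which(ped$orig_id == "5")
  ws <- sire_workspace(ped)
  fj <- evaluate_sire_group(ped, s, j, f, d, ws, reset = FALSE)
  expect_equal(unname(fj), 0.25)
  # seeds: y over ANC_3 = {3, 1, 2} equals d * L = 0.5 each; metafounder 0
  i1 <- which(ped$orig_id == "1"); i2 <- which(ped$orig_id == "2")
  expect_equal(ws$y[c(s, i1, i2)], c(0.5, 0.5, 0.5))
  expect_equal(ws$y[1], 0)                     # gamma = 0 metafounder seed
  expect_equal(ws$y[mate], unname(A["3", "4"]))   # y[d_j] = A_{d_j, s}
  reset_workspace(ws)
  expect_true(all(ws$y == 0) && all(!ws$flag) && !length(ws$touched))

  # sire unrelated to the mate: y[mate] = 0, progeny F = 0
  raw <- raw_pedigree(c("s", "d", "j2"), c(NA, NA, "s"), c(NA, NA, "d"))
  p2 <- build_pedigree(assign_metafounders(raw))
  f2 <- inbreeding(p2, "tabular")$f; d2 <- d_vector(p2, f2)
  ws2 <- sire_workspace(p2)
  s2 <- which(p2$orig_id == "s")
  fj2 <- evaluate_sire_group(p2, s2, which(p2$orig_id == "j2"), f2, d2, ws2)
  expect_equal(unname(fj2), 0)

  # sire = metafounder with gamma 0: all seeds 0, progeny F = 0
  raw3 <- raw_pedigree(c("d3", "j3"), c(NA, "0?"), c(NA, "d3"))
  raw3$sire[2] <- NA
  p3 <- build_pedigree(assign_metafounders(raw3))
  f3 <- inbreeding(p3, "tabular")$f; d3 <- d_vector(p3, f3)
  ws3 <- sire_workspace(p3)
  fj3 <- evaluate_sire_group(p3, 1L, which(p3$orig_id == "j3"), f3, d3, ws3)
  expect_equal(unname(fj3), 0)
})

test_that("y_recurse short-circuits flagged entries and propagates zeros", {
  ped <- toy_fullsib_ped()
  f <- inbreeding(ped, "tabular")$f
  d <- d_vector(ped, f)
  ws <- sire_workspace(ped)
  i1 <- which(ped$orig_id == "1")
  ws$y[i1] <- 0.77; ws$flag[i1] <- TRUE; ws$touched <- i1
  expect_equal(y_recurse(ped, i1, d, ws), 0.77)   # no recomputation
  # unseeded workspace: everything evaluates to zero
  ws2 <- sire_workspace(ped)
  expect_equal(y_recurse(ped, which(ped$orig_id == "5"), d, ws2), 0)
  expect_true(all(ws2$y == 0))
})

test_that("workspace reuse across consecutive sires equals fresh workspaces", {
  p <- random_ped(200, depth = 8, seed = 17)
  A <- tabular_A(p)
  f <- unname(diag(A) - 1); d <- d_vector(p, f)
  sires <- unique(p$sire[!p$is_meta])
  sires <- sires[!p$is_meta[sires]][1:min(6, sum(!p$is_meta[sires]))]
  shared <- sire_workspace(p)
  for (s in sires) {
    prog <- which(!p$is_meta & p$sire == s)
    got <- evaluate_sire_group(p, s, prog, f, d, shared)
    fresh <- evaluate_sire_group(p, s, prog, f, d, sire_workspace(p))
    expect_identical(got, fresh)
    expect_true(all(shared$y == 0) && all(!shared$flag))  # full-scan reset check
  }
})

test_that("MI equals the oracle, the R reference, and recovers Wright's line", {
  ped <- toy_fullsib_ped()
  expect_equal(unname(real_F(ped, inbreeding_MI(ped))["5"]), 0.25)
  for (seed in 1:10) {
    gam <- if (seed %% 2 == 0) 0.2 else 0
    p <- random_ped(250, depth = 12, seed = seed, gamma = gam)
    ft <- inbreeding(p, "tabular")$f
    expect_lt(max(abs(inbreeding_MI(p)$f - ft)), 1e-10)
    expect_lt(max(abs(inbreeding_MI_reference(p)$f - ft)), 1e-10)
  }
  p <- random_ped(2000, depth = 20, seed = 99)
  expect_lt(max(abs(inbreeding_MI(p)$f - inbreeding(p, "tabular")$f)), 1e-10)
  line <- build_pedigree(assign_metafounders(fullsib_line_raw(10)))
  f <- real_F(line, inbreeding_MI(line))
  expect_equal(unname(f[paste0("a", 2:10)]), wright_F(9), tolerance = 1e-12)
})

test_that("every flagged y value during MI equals the tabular A_{i,s}", {
  for (seed in c(4, 23)) {
    p <- random_ped(250, depth = 10, seed = seed,
                    gamma = if (seed == 4) 0 else 0.2)
    A <- tabular_A(p)
    cap <- inbreeding_MI(p, capture_y = TRUE)$capture
    expect_gt(nrow(cap), 0)
    expect_lt(max(abs(cap$y - A[cbind(cap$animal, cap$sire)])), 1e-10)
  }
})

test_that("MI is bitwise deterministic across worker counts", {
  p <- random_ped(3000, depth = 15, seed = 31)
  f1 <- inbreeding_MI(p, workers = 1)
  for (w in c(2, 8)) expect_identical(inbreeding_MI(p, workers = w)$f, f1$f)
  expect_identical(f1$diagnostics,
                   inbreeding_MI(p, workers = 8)$diagnostics)
  expect_error(inbreeding_MI(p, workers = 0), "positive")
})

test_that("MI forward-element count never exceeds the I method's", {
  for (seed in c(3, 14)) {
    p <- random_ped(400, depth = 10, seed = seed)
    mi <- inbreeding_MI(p)$diagnostics$elements_computed_forward
    ii <- inbreeding_I(p)$diagnostics$elements_computed_forward
    expect_lte(mi, ii)
  }
})

test_that("half-sib ancestry reuse makes flagged counts grow sublinearly in mates", {
  # one sire with m mates that are full sibs descending from a 25-deep chain:
  # each mate alone would require flagging its ~27 ancestors, but the chain is
  # shared, so each additional mate adds O(1) flagged entries.
  depth <- 25L
  half_sib_ped <- function(m) {
    id <- paste0("c", 0:depth)
    sire <- c(NA, head(id, -1)); dam <- c(NA, head(id, -1))
    id <- c(id, "fd", "s")
    sire <- c(sire, NA, NA); dam <- c(dam, NA, NA)
    for (k in seq_len(m)) {
      id <- c(id, paste0("mate", k))
      sire <- c(sire, paste0("c", depth)); dam <- c(dam, "fd")
    }
    for (k in seq_len(m)) {
      id <- c(id, paste0("j", k))
      sire <- c(sire, "s"); dam <- c(dam, paste0("mate", k))
    }
    build_pedigree(assign_metafounders(raw_pedigree(id, sire, dam)))
  }
  fwd <- vapply(c(4L, 64L), function(m)
    inbreeding_MI(half_sib_ped(m))$diagnostics$elements_computed_forward,
    numeric(1))
  per_extra_mate <- (fwd[2] - fwd[1]) / (64 - 4)
  expect_lt(per_extra_mate, 5)          # far below the ~27 isolated ancestors
})
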