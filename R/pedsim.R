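## pedsim: synthetic livestock pedigrees under a factorial half-sib mating
## design with generation-size growth and truncation-selection replacement.
##
## Generation sizes follow a fixed schedule: gen1_size in generation 1,
## growing by growth_per_gen per generation up to plateau_size (reached at
## generation 5 under the default numbers).  The active sire count scales
## with the generation size so that the plateau half-sib family size
## (progeny per sire) is constant; each active dam contributes
## litters_per_dam litters of litter_size progeny, each litter by a
## different randomly drawn sire.

#' Simulation design
#'
#' All sizes are animal counts; rates are fractions.  The defaults are
#' filled by [design_from_family_size()]; this constructor validates a
#' fully specified design.
#'
#' @param n_base_sires,n_base_dams base-population (generation 0) counts.
#' @param litters_per_dam litters per active dam and generation (each by a
#'   different sire).
#' @param litter_size progeny per litter.
#' @param gen1_size animals born in generation 1.
#' @param growth_per_gen constant increment of the generation size until the
#'   plateau.
#' @param plateau_size generation size from the plateau onward.
#' @param n_generations number of generations to simulate.
#' @param sire_replacement,dam_replacement fraction of the oldest active
#'   sires/dams replaced each generation.
#' @param heritability narrow-sense h^2 of the selection trait.
#' @param sex_ratio fraction of male progeny.
#' @param seed RNG seed for [simulate_pedigree()].
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(n_base_sires, n_base_dams = 50000L,
                       litters_per_dam = 2L, litter_size = 1L,
                       gen1_size = 100000L, growth_per_gen = 50000L,
                       plateau_size = 300000L, n_generations = 35L,
                       sire_replacement = 0.5, dam_replacement = 0.3,
                       heritability = 0.3, sex_ratio = 0.5, seed = 1L) {
  d <- list(n_base_sires = as.integer(n_base_sires),
            n_base_dams = as.integer(n_base_dams),
            litters_per_dam = as.integer(litters_per_dam),
            litter_size = as.integer(litter_size),
            gen1_size = as.integer(gen1_size),
            growth_per_gen = as.integer(growth_per_gen),
            plateau_size = as.integer(plateau_size),
            n_generations = as.integer(n_generations),
            sire_replacement = sire_replacement,
            dam_replacement = dam_replacement,
            heritability = heritability,
            sex_ratio = sex_ratio,
            seed = as.integer(seed))
  stopifnot(d$n_base_sires >= 2L, d$n_base_dams >= 1L,
            d$litters_per_dam >= 1L, d$litter_size >= 1L,
            d$gen1_size >= 1L, d$plateau_size >= d$gen1_size,
            d$n_generations >= 0L, d$n_generations <= 35L,
            sire_replacement >= 0, sire_replacement <= 1,
            dam_replacement >= 0, dam_replacement <= 1,
            heritability > 0, heritability <= 1,
            sex_ratio > 0, sex_ratio < 1)
  per_dam <- d$litters_per_dam * d$litter_size
  if (d$gen1_size %% per_dam != 0L)
    stop("gen1_size must be a multiple of litters_per_dam * litter_size")
  if (d$gen1_size / per_dam != d$n_base_dams)
    stop("design infeasible: generation 1 needs ", d$gen1_size / per_dam,
         " dams but the base has ", d$n_base_dams)
  class(d) <- "sim_design"
  d
}

#' @export
print.sim_design <- function(x, ...) {
  cat("Simulation design: base", x$n_base_sires, "sires x", x$n_base_dams,
      "dams;", x$n_generations, "generations\n")
  cat("  generation sizes:", x$gen1_size, "growing by", x$growth_per_gen,
      "to", x$plateau_size, "; plateau family size",
      round(x$plateau_size / .sires_active(x, max(5L, x$n_generations)), 2), "\n")
  invisible(x)
}

#' Preset designs by half-sib family size
#'
#' The three evaluation scenarios: plateau family sizes 1000, 200 and 4
#' correspond to 100, 500 and 25,000 base sires (300, 1,500 and 75,000
#' active sires per generation at the plateau) over a base of 50,000 dams.
#'
#' @param family_size one of 1000, 200, 4.
#' @param n_generations generations to simulate (<= 35).
#' @param seed RNG seed.
#' @return A [sim_design()].
#' @export
design_from_family_size <- function(family_size, n_generations = 35L, seed = 1L) {
  base_sires <- switch(as.character(family_size),
                       "1000" = 100L, "200" = 500L, "4" = 25000L,
                       stop("unsupported family size: ", family_size,
                            " (presets: 1000, 200, 4)"))
  sim_design(n_base_sires = base_sires, n_generations = n_generations,
             seed = seed)
}

#' Per-generation census sizes (closed form)
#'
#' @param design a [sim_design()].
#' @param through_generation last generation (default the design's).
#' @return Integer vector of generation sizes for generations
#'   `1..through_generation` (length 0 if 0).
#' @export
expected_generation_sizes <- function(design, through_generation = design$n_generations) {
  g <- seq_len(through_generation)
  as.integer(pmin(design$gen1_size + design$growth_per_gen * (g - 1L),
                  design$plateau_size))
}

#' Total pedigree size (closed form)
#'
#' Base population (sires + dams) plus the sum of the generation sizes; pure
#' arithmetic, no simulation.
#'
#' @inheritParams expected_generation_sizes
#' @return Integer total animal count through `through_generation`.
#' @export
expected_total_animals <- function(design, through_generation = design$n_generations) {
  stopifnot(through_generation >= 0, through_generation <= design$n_generations)
  design$n_base_sires + design$n_base_dams +
    sum(expected_generation_sizes(design, through_generation))
}

#' Scale a design down by an integer divisor
#'
#' Divides all population counts by `divisor`, preserving the family-size
#' and growth ratios; used to exercise the full design structure at test
#' scale.
#'
#' @param design a [sim_design()].
#' @param divisor positive integer dividing all the design's counts.
#' @return A [sim_design()].
#' @export
scale_design <- function(design, divisor) {
  stopifnot(inherits(design, "sim_design"), divisor >= 1)
  cnt <- c("n_base_sires", "n_base_dams", "gen1_size", "growth_per_gen",
           "plateau_size")
  if (any(unlist(design[cnt]) %% divisor != 0))
    stop("divisor must divide all design counts exactly")
  for (f in cnt) design[[f]] <- design[[f]] %/% as.integer(divisor)
  do.call(sim_design, unclass(design))
}

.sires_active <- function(design, g) {
  sz <- expected_generation_sizes(design, g)
  as.integer(round(design$n_base_sires * (sz[g] / design$gen1_size)))
}

#' Simulate a pedigree under a factorial mating design
#'
#' Generation 0 is an unrelated base population.  Each generation, every
#' active dam is mated to `litters_per_dam` distinct random active sires;
#' the progeny census is forced to the closed-form generation sizes by
#' activating exactly the required number of dams.  True breeding values
#' are parent average plus a Mendelian-sampling draw, phenotypes add
#' environmental noise for the design heritability, and each generation the
#' oldest `sire_replacement` / `dam_replacement` fraction of the active
#' sets is replaced (and the sets grown per the schedule) by the
#' highest-phenotype young animals of the previous generation.
#' Reproducible from the design seed.
#'
#' @param design a [sim_design()].
#' @return An object of class `sim_pedigree`: integer vectors `id`, `sire`,
#'   `dam` (0 = base founder slot), `generation`, logical `male`, numeric
#'   `tbv`, `phen`, a per-generation `census` data frame and the `design`.
#' @export
simulate_pedigree <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(design$seed)
  G <- design$n_generations
  sizes <- expected_generation_sizes(design, G)
  n_base <- design$n_base_sires + design$n_base_dams
  total <- n_base + sum(sizes)
  h2 <- design$heritability
  per_dam <- design$litters_per_dam * design$litter_size

  id <- seq_len(total)
  sire <- integer(total); dam <- integer(total)
  generation <- integer(total)
  male <- logical(total); tbv <- numeric(total); phen <- numeric(total)

  bs <- seq_len(design$n_base_sires)
  bd <- design$n_base_sires + seq_len(design$n_base_dams)
  male[bs] <- TRUE
  tbv[seq_len(n_base)] <- rnorm(n_base, 0, sqrt(h2))
  phen[seq_len(n_base)] <- tbv[seq_len(n_base)] + rnorm(n_base, 0, sqrt(1 - h2))

  active_sires <- bs          # oldest first; recruits appended
  active_dams <- bd
  nxt <- n_base + 1L
  census <- data.frame(generation = 0:G,
                       size = c(n_base, sizes),
                       active_sires = NA_integer_, active_dams = NA_integer_)

  top_of <- function(cand, k) {
    if (k > length(cand))
      stop("design infeasible: need ", k, " recruits but only ",
           length(cand), " candidates are available")
    cand[order(-phen[cand], cand)][seq_len(k)]  # ties: lowest id
  }
  refresh <- function(active, target, rate, cand) {
    n_rem <- min(floor(rate * length(active)), length(active))
    kept <- if (n_rem > 0) active[-seq_len(n_rem)] else active
    if (length(kept) > target) kept <- tail(kept, target)   # shrinking designs
    c(kept, top_of(cand, target - length(kept)))
  }

  for (g in seq_len(G)) {
    m <- sizes[g]
    nd <- m %/% per_dam
    ns <- .sires_active(design, g)
    if (g > 1L) {
      prev <- which(generation == (g - 1L))
      active_sires <- refresh(active_sires, ns, design$sire_replacement,
                              prev[male[prev]])
      active_dams <- refresh(active_dams, nd, design$dam_replacement,
                             prev[!male[prev]])
    }
    if (length(active_sires) != ns || length(active_dams) != nd)
      stop("design infeasible at generation ", g)
    if (design$litters_per_dam > length(active_sires))
      stop("design infeasible: fewer active sires than litters per dam")
    census$active_sires[g + 1L] <- ns
    census$active_dams[g + 1L] <- nd

    ## factorial mating: litters_per_dam distinct sires per dam
    smat <- matrix(0L, nrow = nd, ncol = design$litters_per_dam)
    for (l in seq_len(design$litters_per_dam)) {
      s <- sample(active_sires, nd, replace = TRUE)
      if (l > 1L) {
        repeat {
          clash <- which(rowSums(smat[, seq_len(l - 1L), drop = FALSE] == s) > 0)
          if (!length(clash)) break
          s[clash] <- sample(active_sires, length(clash), replace = TRUE)
        }
      }
      smat[, l] <- s
    }
    rows <- seq.int(nxt, nxt + m - 1L)
    dam[rows] <- rep(rep(active_dams, each = design$litter_size),
                     times = design$litters_per_dam)
    sire[rows] <- rep(as.vector(smat), each = design$litter_size)
    generation[rows] <- g
    n_male <- round(design$sex_ratio * m)
    ml <- logical(m); ml[sample.int(m, n_male)] <- TRUE
    male[rows] <- ml
    ## Mendelian-sampling variance h2/2 (parental F terms omitted: affects
    ## only selection composition, see the methods vignette)
    tbv[rows] <- 0.5 * (tbv[sire[rows]] + tbv[dam[rows]]) +
      rnorm(m, 0, sqrt(0.5 * h2))
    phen[rows] <- tbv[rows] + rnorm(m, 0, sqrt(1 - h2))
    nxt <- nxt + m
  }
  structure(list(id = id, sire = sire, dam = dam, generation = generation,
                 male = male, tbv = tbv, phen = phen,
                 census = census, design = design),
            class = "sim_pedigree")
}

#' @export
print.sim_pedigree <- function(x, ...) {
  cat("Simulated pedigree:", length(x$id), "animals over",
      x$design$n_generations, "generations (base",
      x$design$n_base_sires, "sires x", x$design$n_base_dams, "dams)\n")
  invisible(x)
}

#' Convert a simulated pedigree to raw records
#'
#' Birth years are the generation numbers.  Base animals keep unknown
#' parents; pass the result through [assign_metafounders()] (or
#' [prepare_pedigree()]) before building.
#'
#' @param sim a [simulate_pedigree()] result.
#' @return A [raw_pedigree()].
#' @export
sim_to_raw <- function(sim) {
  stopifnot(inherits(sim, "sim_pedigree"))
  idc <- as.character(sim$id)
  pc <- function(p) ifelse(p == 0L, NA_character_, as.character(p))
  raw_pedigree(idc, pc(sim$sire), pc(sim$dam), sim$generation)
}
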