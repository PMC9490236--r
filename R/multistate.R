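## Multistate (chameleonic) design -------------------------------------------
##
## A genetic algorithm over hydrophobic point mutations that drives a
## sequence towards two isoenergetic states on two fixed backbones, scored
## by the fitness (-5*|eA - eB|) - (eA - eB).  The fitness is bounded above
## by 0, attained exactly when eA = eB: writing D = eA - eB, the score is
## -4D for D < 0 and -6D for D > 0, both strictly negative away from zero.

#' GA parameters
#'
#' Reference-scale values are population 1000, survivors 500, 1000
#' generations with per-backbone energy ceiling 10 and inter-state gap
#' ceiling 6 score units; the constructor defaults are desk-scale.
#'
#' @param population initial variant count.
#' @param survivors sequences carried to the next generation.
#' @param generations number of generations.
#' @param energy_ceiling per-backbone threaded-energy ceiling (score units).
#' @param gap_ceiling |eA - eB| ceiling (score units).
#' @param init_mutations range of point mutations in initial variants.
#' @return A `ga_params` list.
#' @export
ga_params <- function(population = 60, survivors = 30, generations = 50,
                      energy_ceiling = 10, gap_ceiling = 6,
                      init_mutations = c(1, 3)) {
  stopifnot(survivors <= population, energy_ceiling > 0, gap_ceiling > 0)
  structure(list(population = as.integer(population),
                 survivors = as.integer(survivors),
                 generations = as.integer(generations),
                 energy_ceiling = energy_ceiling,
                 gap_ceiling = gap_ceiling,
                 init_mutations = init_mutations),
            class = "ga_params")
}

#' Reference-scale GA parameters
#' @return [ga_params()] with population 1000, survivors 500, 1000
#'   generations.
#' @export
ga_params_reference <- function() {
  ga_params(population = 1000, survivors = 500, generations = 1000)
}

#' Multistate fitness
#'
#' Exactly `(-5 * abs(eA - eB)) - (eA - eB)`.  Larger is better; the maximum
#' 0 is attained iff eA = eB.
#'
#' @param eA,eB threaded energies of a sequence on the two backbones.
#' @return Fitness (score units, <= 0).
#' @export
ga_fitness <- function(eA, eB) {
  stopifnot(is.finite(eA), is.finite(eB))
  (-5 * abs(eA - eB)) - (eA - eB)
}

#' Multistate energy filter
#'
#' True iff both threaded energies are below the per-backbone ceiling and
#' their difference is below the gap ceiling.
#'
#' @param eA,eB threaded energies.
#' @param params a [ga_params()].
#' @return Logical.
#' @export
ga_filter <- function(eA, eB, params = ga_params()) {
  eA < params$energy_ceiling && eB < params$energy_ceiling &&
    abs(eA - eB) < params$gap_ceiling
}

#' Thread a sequence onto a fixed backbone and score it
#'
#' Swaps identities onto the backbone's torsions, briefly relaxes the
#' structure in torsion space, and returns the total surrogate energy.
#' Deterministic for fixed inputs.
#'
#' @param seq a [macrocycle_sequence()] (length must match).
#' @param backbone a `cycpep_conformation`.
#' @param weights weight set.
#' @param relax_iter torsion-space relaxation iterations (0 = rigid thread).
#' @return Total energy (score units).
#' @export
thread_and_score <- function(seq, backbone, weights = "standard",
                             relax_iter = 5) {
  if (nrow(seq) != nrow(backbone$seq)) stop("sequence/backbone length mismatch")
  conf <- thread_sequence(backbone, seq)
  if (relax_iter > 0) {
    minimize_conformation(conf, weights, max_iter = relax_iter)$energy
  } else {
    score_conformation(conf, weights)$total
  }
}

## mutable positions and identity choices, maintaining chirality and
## N-methylation patterns (proline positions are left untouched and proline
## is never introduced, since that would alter the donor pattern)
ga_choices <- function(start_seq) {
  alpha <- design_alphabets()
  lapply(seq_len(nrow(start_seq)), function(i) {
    if (start_seq$aa[i] %in% c("PRO", "GLY", "AIB")) return(character(0))
    pool <- if (start_seq$chirality[i] == "D") alpha$D else alpha$L
    setdiff(pool, "PRO")
  })
}

mutate_seq <- function(aa, choices, k = 1L) {
  mutable <- which(lengths(choices) > 1)
  if (!length(mutable)) return(aa)
  pos <- sample(mutable, min(k, length(mutable)))
  for (i in pos) {
    alt <- setdiff(choices[[i]], aa[i])
    if (length(alt)) aa[i] <- alt[sample.int(length(alt), 1)]
  }
  aa
}

#' Genetic-algorithm multistate design
#'
#' Initialises a population of hydrophobic point mutants of the starting
#' sequence (chirality and N-methylation patterns preserved), threads and
#' scores every variant on both backbones, discards variants failing
#' [ga_filter()], ranks the rest by [ga_fitness()] (ties by lower eA + eB,
#' then lexicographic sequence), carries the best `survivors` forward and
#' adds one point mutant per survivor.  If a generation filters out every
#' variant, the population is rebuilt from survivor mutants and a warning is
#' logged.  Deterministic under a fixed seed.
#'
#' @param start_seq a [macrocycle_sequence()].
#' @param backbone_A,backbone_B the two target `cycpep_conformation`s.
#' @param params a [ga_params()].
#' @param rng_seed integer seed.
#' @param energy_fn custom energy function `f(aa_vector)` returning
#'   `c(eA, eB)`; defaults to [thread_and_score()] on both backbones.
#' @param weights weight set for the default energy function.
#' @param choices optional per-position identity pools overriding the
#'   default chirality-restricted hydrophobic alphabets.
#' @return List with `best` (a `ga_variant`: sequence, eA, eB, fitness) and
#'   `log` (per-generation data frame: generation, best_fitness, eA, eB,
#'   sequence, n_pass).
#' @export
run_multistate_ga <- function(start_seq, backbone_A = NULL, backbone_B = NULL,
                              params = ga_params(), rng_seed = 1,
                              energy_fn = NULL, weights = "standard",
                              choices = NULL) {
  set.seed(rng_seed)
  if (is.null(choices)) choices <- ga_choices(start_seq)
  if (is.null(energy_fn)) {
    stopifnot(!is.null(backbone_A), !is.null(backbone_B))
    cache <- new.env(parent = emptyenv())
    energy_fn <- function(aa) {
      key <- paste(aa, collapse = ".")
      hit <- cache[[key]]
      if (!is.null(hit)) return(hit)
      s2 <- macrocycle_sequence(aa, start_seq$chirality, start_seq$n_methyl,
                                strict = FALSE)
      v <- c(thread_and_score(s2, backbone_A, weights),
             thread_and_score(s2, backbone_B, weights))
      cache[[key]] <- v
      v
    }
  }
  nm <- sample(params$init_mutations[1]:params$init_mutations[2],
               params$population, replace = TRUE)
  pop <- lapply(seq_len(params$population), function(k) {
    mutate_seq(start_seq$aa, choices, nm[k])
  })
  log <- NULL
  best_overall <- NULL
  for (gen in seq_len(params$generations)) {
    pop <- unique(pop)
    sc <- t(vapply(pop, energy_fn, numeric(2)))
    fit <- ga_fitness_vec(sc[, 1], sc[, 2])
    pass <- sc[, 1] < params$energy_ceiling & sc[, 2] < params$energy_ceiling &
      abs(sc[, 1] - sc[, 2]) < params$gap_ceiling
    if (!any(pass)) {
      warning("generation ", gen, ": no variant passed the energy filter; ",
              "repopulating from mutants")
      pop <- lapply(pop[seq_len(min(length(pop), params$survivors))],
                    function(aa) mutate_seq(aa, choices, 1L))
      next
    }
    idx <- which(pass)
    seqstr <- vapply(pop[idx], paste, character(1), collapse = "")
    ord <- idx[order(-fit[idx], sc[idx, 1] + sc[idx, 2], seqstr)]
    keep <- ord[seq_len(min(params$survivors, length(ord)))]
    top <- keep[1]
    cand <- list(aa = pop[[top]], eA = sc[top, 1], eB = sc[top, 2],
                 fitness = fit[top])
    if (is.null(best_overall) || cand$fitness > best_overall$fitness ||
        (cand$fitness == best_overall$fitness &&
         cand$eA + cand$eB < best_overall$eA + best_overall$eB)) {
      best_overall <- cand
    }
    log <- rbind(log, data.frame(generation = gen,
                                 best_fitness = fit[top],
                                 eA = sc[top, 1], eB = sc[top, 2],
                                 sequence = paste(pop[[top]], collapse = "-"),
                                 n_pass = sum(pass),
                                 stringsAsFactors = FALSE))
    survivors <- pop[keep]
    mutants <- lapply(survivors, function(aa) mutate_seq(aa, choices, 1L))
    pop <- c(survivors, mutants)
  }
  if (is.null(best_overall)) {
    stop("GA terminated without any variant passing the filter")
  }
  best_seq <- macrocycle_sequence(best_overall$aa, start_seq$chirality,
                                  start_seq$n_methyl, strict = FALSE)
  best <- structure(list(sequence = best_seq, eA = best_overall$eA,
                         eB = best_overall$eB,
                         fitness = best_overall$fitness),
                    class = "ga_variant")
  list(best = best, log = log)
}

ga_fitness_vec <- function(eA, eB) (-5 * abs(eA - eB)) - (eA - eB)

#' @export
print.ga_variant <- function(x, ...) {
  cat(sprintf("GA variant %s: eA %.3f, eB %.3f, fitness %.3f\n",
              sequence_string(x$sequence), x$eA, x$eB, x$fitness))
  invisible(x)
}

#' Mutation scan for conformation-switch candidates
#'
#' Loops over every position and allowed hydrophobic identity (chirality and
#' N-methylation maintained), relaxes each mutant, predicts a reduced energy
#' landscape, clusters it, and reports mutants whose landscape contains two
#' or more states within the isoenergetic threshold, annotated by whether
#' the states differ by a cis/trans flip.
#'
#' @param design a `design_record` (or a `cycpep_conformation`).
#' @param n_samples landscape samples per mutant (reduced scale).
#' @param rng_seed integer seed.
#' @param threshold isoenergetic gap threshold (score units).
#' @param rmsd_cutoff clustering radius.
#' @param include_original also evaluate the unmutated sequence.
#' @param minimize_iter relaxation iterations per mutant and per landscape
#'   point (reduced desk scale).
#' @return Data frame with one row per evaluated variant: `position`,
#'   `identity`, `n_states`, `min_gap`, `cis_trans_switch`, `candidate`.
#' @export
switch_scan <- function(design, n_samples = 20, rng_seed = 1, threshold = 5,
                        rmsd_cutoff = 1.0, include_original = TRUE,
                        minimize_iter = 15) {
  conf <- if (inherits(design, "design_record")) design$conformation else design
  seq <- conf$seq
  choices <- ga_choices(seq)
  variants <- list()
  if (include_original) {
    variants[[1]] <- list(position = 0L, identity = "original", aa = seq$aa)
  }
  for (i in seq_len(nrow(seq))) {
    for (aa2 in setdiff(choices[[i]], seq$aa[i])) {
      aa <- seq$aa
      aa[i] <- aa2
      variants[[length(variants) + 1]] <- list(position = i, identity = aa2,
                                               aa = aa)
    }
  }
  out <- NULL
  for (k in seq_along(variants)) {
    v <- variants[[k]]
    s2 <- macrocycle_sequence(v$aa, seq$chirality, seq$n_methyl,
                              strict = FALSE)
    conf2 <- minimize_conformation(thread_sequence(conf, s2),
                                   max_iter = minimize_iter)$conformation
    ls <- predict_landscape(s2, conf2, n_samples, rng_seed + k,
                            minimize_iter = minimize_iter)
    cl <- energy_based_cluster(ls, n_lowest = NULL, rmsd_cutoff = rmsd_cutoff)
    iso <- detect_isoenergetic_states(cl, threshold)
    out <- rbind(out, data.frame(
      position = v$position, identity = v$identity,
      n_states = length(unique(cl$cluster)),
      min_gap = if (nrow(iso)) min(iso$delta_energy) else NA_real_,
      cis_trans_switch = if (nrow(iso)) any(iso$cis_trans_switch) else FALSE,
      candidate = nrow(iso) > 0,
      stringsAsFactors = FALSE))
  }
  out
}
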