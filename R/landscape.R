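## Energy landscapes and structure comparison -------------------------------

#' Symmetry-aware backbone heavy-atom RMSD
#'
#' Least-squares rigid (proper rotation) superposition RMSD over the
#' backbone heavy atoms N, CA, C, O plus the N-methyl carbon CN at positions
#' where both conformations carry one.  Optionally minimised over cyclic
#' relabelings of the starting residue and/or the mirror image (handled by
#' explicit reflection followed by proper superposition, never by an
#' improper rotation).
#'
#' @param a,b `cycpep_conformation`s of equal length.
#' @param allow_cyclic_perm minimise over the n cyclic permutations.
#' @param allow_mirror also compare against the mirror image of `b`.
#' @return RMSD in Angstrom.
#' @export
backbone_rmsd <- function(a, b, allow_cyclic_perm = FALSE,
                          allow_mirror = FALSE) {
  n <- nrow(a$seq)
  if (nrow(b$seq) != n) stop("conformations differ in length")
  shifts <- if (allow_cyclic_perm) 0:(n - 1) else 0L
  bs <- list(b)
  if (allow_mirror) bs <- c(bs, list(mirror_conformation(b)))
  best <- Inf
  for (bb in bs) {
    for (k in shifts) {
      bk <- if (k == 0) bb else cyclic_permute(bb, k)
      r <- rmsd_pair(a, bk)
      if (!is.na(r) && r < best) best <- r
    }
  }
  best
}

rmsd_pair <- function(a, b) {
  atoms <- c("N", "CA", "C", "O", "CN")
  P <- NULL; Q <- NULL
  n <- nrow(a$seq)
  for (i in seq_len(n)) for (atom in atoms) {
    pa <- a$coords[i, atom, ]; pb <- b$coords[i, atom, ]
    if (atom == "CN" && (anyNA(pa) || anyNA(pb))) next
    if (anyNA(pa) || anyNA(pb)) {
      stop("atom ", atom, " missing at residue ", i)
    }
    P <- rbind(P, pa); Q <- rbind(Q, pb)
  }
  kabsch(P, Q)$rmsd
}

#' Torsion-space energy minimisation
#'
#' Local descent of the weighted surrogate total (with the chainbreak term
#' active, which keeps the ring from opening) over all backbone torsions.
#' The output energy never exceeds the input energy; non-convergence within
#' `max_iter` returns the best conformation seen.
#'
#' @param conf a closed `cycpep_conformation`.
#' @param weights weight set, see [weight_set()].
#' @param max_iter maximum BFGS iterations.
#' @return List with `conformation`, `energy` (final total), `initial`
#'   (starting total) and `converged`.
#' @export
minimize_conformation <- function(conf, weights = "standard", max_iter = 50) {
  seq <- conf$seq
  n <- nrow(seq)
  x0 <- as.numeric(conf$torsions)
  obj <- function(x) {
    tor <- matrix(x, n, 3, dimnames = list(NULL, c("phi", "psi", "omega")))
    cf <- build_from_torsions(seq, tor)
    score_conformation(cf, weights)$total
  }
  e0 <- obj(x0)
  o <- stats::optim(x0, obj, method = "BFGS",
                    control = list(maxit = max_iter, reltol = 1e-10))
  if (o$value <= e0) {
    tor <- matrix(o$par, n, 3, dimnames = list(NULL, c("phi", "psi", "omega")))
    out <- build_from_torsions(seq, wrap_angle(tor))
    list(conformation = out, energy = o$value, initial = e0,
         converged = o$convergence == 0)
  } else {
    list(conformation = conf, energy = e0, initial = e0, converged = FALSE)
  }
}

## omega (cis/trans) signature: "t" for trans-like, "c" for cis-like
omega_signature <- function(conf) {
  om <- conf$torsions[, "omega"]
  paste(ifelse(abs(wrap_angle(om)) < 90, "c", "t"), collapse = "")
}

#' Predict the energy landscape of a macrocycle sequence
#'
#' Samples closed backbones for the fixed sequence (no design), minimises
#' each, scores it, and computes the backbone RMSD to the design model
#' (without cyclic-permutation or mirror credit).  The local minimisation of
#' the design model itself is always included and labelled `LE_0`.
#'
#' @param seq a [macrocycle_sequence()].
#' @param design_ref the design-model `cycpep_conformation`.
#' @param n_samples number of sampled conformations (0 = only LE_0).
#' @param rng_seed integer seed.
#' @param policy sampling acceptance policy (hydrogen-bond minimum etc.).
#' @param attempts_per_sample closure attempts allowed per accepted sample.
#' @param minimize_iter iterations of per-sample minimisation.
#' @param weights scoring weight set.
#' @return A `landscape` object: list with `points` (data frame: id, energy,
#'   rmsd, omega_signature, is_design) and `summary` (a `funnel_summary`).
#' @export
predict_landscape <- function(seq, design_ref, n_samples, rng_seed,
                              policy = backbone_acceptance_policy(
                                min_hbonds = 0, cis_probability = 0.15),
                              attempts_per_sample = 30,
                              minimize_iter = 25,
                              weights = "standard") {
  le0 <- minimize_conformation(design_ref, weights, minimize_iter)
  pts <- data.frame(id = "LE_0_design",
                    energy = le0$energy,
                    rmsd = backbone_rmsd(le0$conformation, design_ref),
                    omega_signature = omega_signature(le0$conformation),
                    is_design = TRUE, stringsAsFactors = FALSE)
  confs <- list(le0$conformation)
  if (n_samples > 0) {
    samples <- sample_cyclic_backbones(seq, n_samples * attempts_per_sample,
                                       rng_seed, policy)
    samples <- samples[seq_len(min(length(samples), n_samples))]
    for (k in seq_along(samples)) {
      mm <- minimize_conformation(samples[[k]], weights, minimize_iter)
      confs[[length(confs) + 1]] <- mm$conformation
      pts <- rbind(pts, data.frame(
        id = paste0("S", k),
        energy = mm$energy,
        rmsd = backbone_rmsd(mm$conformation, design_ref),
        omega_signature = omega_signature(mm$conformation),
        is_design = FALSE, stringsAsFactors = FALSE))
    }
  }
  structure(list(points = pts, conformations = confs,
                 summary = funnel_summary(pts)),
            class = "landscape")
}

#' Summarise a funnel: lowest point and the design-basin energy gap
#'
#' The energy gap dE is defined as the energy of the lowest point with RMSD
#' to the design above `basin_rmsd` minus the energy of the lowest point at
#' or below it (positive = the design basin is lowest).
#'
#' @param points landscape point data frame.
#' @param basin_rmsd the RMSD split between design-proximal and alternative
#'   states (Angstrom).
#' @return A `funnel_summary` list.
#' @export
funnel_summary <- function(points, basin_rmsd = 2.0) {
  lowest <- points[which.min(points$energy), , drop = FALSE]
  inb <- points$rmsd <= basin_rmsd
  dE <- if (any(inb) && any(!inb)) {
    min(points$energy[!inb]) - min(points$energy[inb])
  } else NA_real_
  structure(list(lowest = lowest, delta_e = dE, basin_rmsd = basin_rmsd),
            class = "funnel_summary")
}

#' Greedy energy-based leader clustering
#'
#' Repeatedly takes the lowest-energy unassigned structure as a cluster
#' centre and assigns every structure within `rmsd_cutoff` of it.  Clusters
#' are labelled LE_1, LE_2, ... by the energy rank of their centre (ties are
#' broken by input index, so labels are stable under shuffling).  When the
#' point set carries a design-minimisation point it is labelled LE_0.
#'
#' @param landscape a `landscape` object, or a list of conformations plus
#'   an `energies` vector.
#' @param n_lowest cluster only the n lowest-energy structures (NULL = all;
#'   the figure-legend convention is 250 or 500).
#' @param rmsd_cutoff cluster assignment radius (Angstrom).
#' @param energies optional energies when `landscape` is a plain list.
#' @return Data frame with columns `id`, `energy`, `rmsd`, `cluster`
#'   (LE_X labels), `center` (logical).
#' @export
energy_based_cluster <- function(landscape, n_lowest = 250, rmsd_cutoff = 1.0,
                                 energies = NULL) {
  if (inherits(landscape, "landscape")) {
    confs <- landscape$conformations
    pts <- landscape$points
  } else {
    confs <- landscape
    stopifnot(!is.null(energies), length(energies) == length(confs))
    pts <- data.frame(id = paste0("S", seq_along(confs)), energy = energies,
                      rmsd = NA_real_,
                      omega_signature = vapply(confs, omega_signature,
                                               character(1)),
                      is_design = rep(FALSE, length(confs)),
                      stringsAsFactors = FALSE)
  }
  stopifnot(length(confs) >= 1)
  ord <- order(pts$energy, seq_len(nrow(pts)))
  if (!is.null(n_lowest)) ord <- ord[seq_len(min(n_lowest, length(ord)))]
  pts <- pts[ord, , drop = FALSE]
  confs <- confs[ord]
  m <- nrow(pts)
  cluster <- rep(NA_integer_, m)
  centers <- integer()
  for (k in seq_len(m)) {
    if (!is.na(cluster[k])) next
    centers <- c(centers, k)
    cid <- length(centers)
    cluster[k] <- cid
    for (j in seq_len(m)) {
      if (!is.na(cluster[j])) next
      if (backbone_rmsd(confs[[k]], confs[[j]]) <= rmsd_cutoff) {
        cluster[j] <- cid
      }
    }
  }
  has_design <- any(pts$is_design)
  label <- if (has_design) {
    design_cl <- cluster[which(pts$is_design)[1]]
    ifelse(cluster == design_cl, "LE_0",
           paste0("LE_", ifelse(cluster > design_cl, cluster - 1, cluster)))
  } else paste0("LE_", cluster)
  out <- data.frame(id = pts$id, energy = pts$energy, rmsd = pts$rmsd,
                    cluster = label,
                    center = seq_len(m) %in% centers,
                    omega_signature = pts$omega_signature,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Detect near-isoenergetic alternative states
#'
#' Pairs of cluster minima whose energy difference is below `threshold`
#' (default 5 score units), annotated by whether their omega signatures
#' differ -- i.e. the two states are separated by a cis/trans peptide-bond
#' flip.
#'
#' @param clusters output of [energy_based_cluster()].
#' @param threshold score-unit gap below which two states count as
#'   isoenergetic.
#' @return Data frame with one row per reported pair: `state_a`, `state_b`,
#'   `delta_energy`, `cis_trans_switch`.
#' @export
detect_isoenergetic_states <- function(clusters, threshold = 5) {
  mins <- do.call(rbind, lapply(split(clusters, clusters$cluster), function(g) {
    g[which.min(g$energy), , drop = FALSE]
  }))
  mins <- mins[order(mins$energy), , drop = FALSE]
  out <- data.frame(state_a = character(), state_b = character(),
                    delta_energy = numeric(), cis_trans_switch = logical(),
                    stringsAsFactors = FALSE)
  if (nrow(mins) < 2) return(out)
  for (i in seq_len(nrow(mins) - 1)) for (j in (i + 1):nrow(mins)) {
    dE <- abs(mins$energy[j] - mins$energy[i])
    if (dE < threshold) {
      sw <- !identical(mins$omega_signature[i], mins$omega_signature[j])
      out <- rbind(out, data.frame(state_a = mins$cluster[i],
                                   state_b = mins$cluster[j],
                                   delta_energy = dE,
                                   cis_trans_switch = sw,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

#' Write landscape points to TSV / funnel summary to JSON
#'
#' @param landscape a `landscape` object.
#' @param tsv_path,json_path output paths (NULL = skip).
#' @return Invisibly, the paths written.
#' @export
write_landscape <- function(landscape, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(landscape$points, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    s <- landscape$summary
    jsonlite::write_json(list(lowest_id = s$lowest$id,
                              lowest_energy = s$lowest$energy,
                              delta_e = s$delta_e,
                              basin_rmsd = s$basin_rmsd),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(tsv_path, json_path))
}
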