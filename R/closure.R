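## Analytic kinematic closure -----------------------------------------------
##
## Tripeptide (triangle) formulation: the three pivot CA atoms split the ring
## into three rigid bodies (all bond lengths/angles ideal, all non-pivot
## torsions fixed, the segment spanning the formal cut built with the ideal
## closure-bond geometry).  The CA-CA virtual-bond lengths are therefore
## fixed, the pivot CAs form a rigid triangle, and each body retains one
## rotational degree of freedom tau_k about its virtual-bond axis.  The
## N-CA-C bond angle constraint at each pivot couples consecutive taus
## through an equation linear in (cos tau, sin tau) of each; the system is
## solved by branch-tracked scanning of tau_1 with bisection refinement,
## which recovers every real solution (at most 16).

#' Define a ring-closure problem
#'
#' @param seq a [macrocycle_sequence()].
#' @param torsions n x 3 matrix of (phi, psi, omega); the phi/psi entries of
#'   the pivot residues are ignored (they are solved for), all others are
#'   fixed.  All omegas are fixed.
#' @param pivots three distinct residue indices whose phi/psi are solved
#'   analytically (six degrees of freedom).
#' @param anchor optional anchor residue index; must not be a pivot.
#' @return A `closure_problem` object.
#' @export
closure_problem <- function(seq, torsions, pivots, anchor = NULL) {
  n <- nrow(seq)
  pivots <- sort(unique(as.integer(pivots)))
  if (length(pivots) != 3) stop("exactly three distinct pivots required")
  if (any(pivots < 1 | pivots > n)) stop("pivot index out of range")
  if (!is.null(anchor) && anchor %in% pivots) {
    stop("the anchor residue cannot be a pivot")
  }
  torsions <- wrap_angle(as.matrix(torsions))
  dimnames(torsions) <- list(NULL, c("phi", "psi", "omega"))
  structure(list(seq = seq, torsions = torsions, pivots = pivots,
                 anchor = anchor), class = "closure_problem")
}

## Build the rigid body running from pivot `from` to pivot `to` (cyclic,
## forward) in a local frame.  Returns anchor points A (CA from), B (CA to),
## the CA->C vector at the start, the CA->N vector at the end, and all placed
## backbone atoms keyed by residue/atom for reconstruction.
build_segment <- function(seq, tor, from, to) {
  g <- .ideal
  n <- nrow(seq)
  atoms <- list()
  put <- function(res, atom, xyz) atoms[[paste(atom, res)]] <<- xyz
  CA <- c(0, 0, 0)
  C <- c(g$b_ca_c, 0, 0)
  C_start <- C
  put(from, "CA", CA)
  put(from, "C", C)
  A0 <- c(0, 1, 0)  # gauge reference for the first azimuth
  r <- from
  Nn <- nerf_place(A0, CA, C, g$b_c_n, g$a_ca_c_n, 0)
  repeat {
    s <- cyc_next(r, n)
    put(s, "N", Nn)
    CAn <- nerf_place(CA, C, Nn, g$b_n_ca, g$a_c_n_ca, tor[r, "omega"])
    put(s, "CA", CAn)
    if (s == to) {
      return(list(A = c(0, 0, 0), B = CAn,
                  cvec = C_start,        # CA(from) -> C(from), A at origin
                  nvec = Nn - CAn,       # CA(to) -> N(to)
                  atoms = atoms))
    }
    Cn <- nerf_place(C, Nn, CAn, g$b_ca_c, g$a_n_ca_c, tor[s, "phi"])
    put(s, "C", Cn)
    Nn2 <- nerf_place(Nn, CAn, Cn, g$b_c_n, g$a_ca_c_n, tor[s, "psi"])
    CA <- CAn; C <- Cn; Nn <- Nn2; r <- s
  }
}

## Fast backbone-only chain build: N/CA/C coordinates plus the ideal
## continuation images of N(1), CA(1), C(1).  Used for solution polishing.
bb_chain_images <- function(tor) {
  g <- .ideal
  n <- nrow(tor)
  N <- matrix(0, n, 3); CA <- matrix(0, n, 3); C <- matrix(0, n, 3)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  th <- g$a_c_n_ca * .deg2rad
  C0 <- c(g$b_c_n * cos(th), g$b_c_n * sin(th), 0)
  C[1, ] <- nerf_place(C0, N[1, ], CA[1, ], g$b_ca_c, g$a_n_ca_c, tor[1, 1])
  for (i in seq_len(n - 1)) {
    N[i + 1, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], g$b_c_n, g$a_ca_c_n,
                             tor[i, 2])
    CA[i + 1, ] <- nerf_place(CA[i, ], C[i, ], N[i + 1, ], g$b_n_ca,
                              g$a_c_n_ca, tor[i, 3])
    C[i + 1, ] <- nerf_place(C[i, ], N[i + 1, ], CA[i + 1, ], g$b_ca_c,
                             g$a_n_ca_c, tor[i + 1, 1])
  }
  Nim <- nerf_place(N[n, ], CA[n, ], C[n, ], g$b_c_n, g$a_ca_c_n, tor[n, 2])
  CAim <- nerf_place(CA[n, ], C[n, ], Nim, g$b_n_ca, g$a_c_n_ca, tor[n, 3])
  Cim <- nerf_place(C[n, ], Nim, CAim, g$b_ca_c, g$a_n_ca_c, tor[1, 1])
  list(N = N, CA = CA, C = C, Nim = Nim, CAim = CAim, Cim = Cim)
}

## Squared closure gap over the three image atoms (full rigid-continuation
## consistency, including the azimuth of the first carbonyl).
closure_gap <- function(tor) {
  b <- bb_chain_images(tor)
  sum((b$Nim - b$N[1, ])^2) + sum((b$CAim - b$CA[1, ])^2) +
    sum((b$Cim - b$C[1, ])^2)
}

## Local refinement of the six pivot torsions against the exact closure gap.
polish_pivots <- function(tor, pv) {
  f <- function(x) {
    tor[pv, 1:2] <- matrix(x, 3, 2, byrow = TRUE)
    closure_gap(tor)
  }
  x0 <- as.numeric(t(tor[pv, 1:2]))
  o <- stats::optim(x0, f, method = "BFGS",
                    control = list(maxit = 30, reltol = 1e-16))
  if (o$value < f(x0)) {
    tor[pv, 1:2] <- matrix(o$par, 3, 2, byrow = TRUE)
  }
  wrap_angle(tor)
}

## Rotation matrix taking unit vector u onto unit vector e.
align_rotation <- function(u, e) {
  d <- sum(u * e)
  if (d > 1 - 1e-12) return(diag(3))
  if (d < -1 + 1e-12) {
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- unitv(cross3(u, p))
    return(rodrigues_matrix(ax, 180))
  }
  ax <- unitv(cross3(u, e))
  rodrigues_matrix(ax, acos(d) / .deg2rad)
}

rodrigues_matrix <- function(e, theta) {
  th <- theta * .deg2rad
  K <- matrix(c(0, e[3], -e[2], -e[3], 0, e[1], e[2], -e[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## Rodrigues decomposition: Rot(e, tau) v = a + b cos(tau) + c sin(tau)
rod_abc <- function(v, e) {
  a <- e * sum(e * v)
  rbind(a, v - a, cross3(e, v))
}

#' Solve a ring-closure problem analytically
#'
#' Returns every real solution of the tripeptide closure system.  Each
#' solution is a closed conformation whose closure bond reproduces the ideal
#' closure geometry (bond length 1.328685 A, flanking angles 121.69997 /
#' 116.199993 deg) to within numerical tolerance.
#'
#' @param problem a [closure_problem()].
#' @param grid_size number of tau_1 scan points (resolution of root
#'   bracketing).
#' @param thorough scan from all three driver taus and refine tangent /
#'   domain-edge roots (full solution set; the default).  `FALSE` runs a
#'   single-driver sign-change scan, sufficient when any one closed
#'   solution is wanted quickly (e.g. backbone sampling).
#' @return A `closure_solutions` object: list with `solutions` (list of
#'   closed `cycpep_conformation`s) and `pivot_torsions` (matrix of the six
#'   solved angles per solution, columns phi1, psi1, phi2, psi2, phi3, psi3).
#' @export
solve_closure <- function(problem, grid_size = 720, thorough = TRUE) {
  seq <- problem$seq
  tor <- problem$torsions
  pv <- problem$pivots
  n <- nrow(seq)
  segs <- list(build_segment(seq, tor, pv[1], pv[2]),
               build_segment(seq, tor, pv[2], pv[3]),
               build_segment(seq, tor, pv[3], pv[1]))
  d <- vapply(segs, function(s) vnorm(s$B - s$A), numeric(1))
  empty <- structure(list(solutions = list(),
                          pivot_torsions = matrix(numeric(), 0, 6)),
                     class = "closure_solutions")
  ## triangle feasibility
  if (d[1] > d[2] + d[3] || d[2] > d[1] + d[3] || d[3] > d[1] + d[2]) {
    return(empty)
  }
  V <- matrix(0, 3, 3)
  V[2, ] <- c(d[1], 0, 0)
  x3 <- (d[1]^2 + d[3]^2 - d[2]^2) / (2 * d[1])
  y3sq <- d[3]^2 - x3^2
  V[3, ] <- c(x3, sqrt(max(0, y3sq)), 0)
  e <- rbind(unitv(V[2, ] - V[1, ]),
             unitv(V[3, ] - V[2, ]),
             unitv(V[1, ] - V[3, ]))
  R <- lapply(1:3, function(k) align_rotation(unitv(segs[[k]]$B - segs[[k]]$A),
                                              e[k, ]))
  K <- cos(.ideal$a_n_ca_c * .deg2rad)
  ## vertex i constraint: p from body i-1 (axis e_{i-1}), q from body i (axis e_i)
  prev <- c(3, 1, 2)
  Mv <- vector("list", 3)
  for (i in 1:3) {
    pm <- prev[i]
    p <- as.numeric(R[[pm]] %*% segs[[pm]]$nvec)
    q <- as.numeric(R[[i]] %*% segs[[i]]$cvec)
    P <- rod_abc(p, e[pm, ])
    Q <- rod_abc(q, e[i, ])
    M <- P %*% t(Q)
    M[1, 1] <- M[1, 1] - K * vnorm(p) * vnorm(q)
    Mv[[i]] <- M
  }
  ## branch solver: given f-sigma rows (G x 3) and vertex matrix M, return
  ## the two tau branches (degrees) or NA where no real solution.
  solve_tau <- function(fs, M) {
    co <- fs %*% M   # G x 3: A, B, C
    A <- co[, 1]; B <- co[, 2]; C <- co[, 3]
    R0 <- sqrt(B^2 + C^2)
    val <- -A / R0
    bad <- !is.finite(val) | abs(val) > 1
    val[val > 1] <- 1
    val[val < -1] <- -1
    delta <- atan2(C, B)
    acv <- acos(val)
    t1 <- (delta + acv) / .deg2rad
    t2 <- (delta - acv) / .deg2rad
    t1[bad] <- NA_real_
    t2[bad] <- NA_real_
    cbind(t1, t2)
  }
  fs_of <- function(tau) cbind(1, cos(tau * .deg2rad), sin(tau * .deg2rad))
  ## chained solve starting from driver vertex d: given tau_d, solve the next
  ## two vertex equations branch-wise and return the residual of vertex d.
  residual_chain <- function(taud, d, ba, bb) {
    i1 <- d %% 3 + 1
    i2 <- i1 %% 3 + 1
    ta <- solve_tau(fs_of(taud), Mv[[i1]])[, ba]
    tb <- solve_tau(fs_of(ta), Mv[[i2]])[, bb]
    rowSums((fs_of(tb) %*% Mv[[d]]) * fs_of(taud))
  }
  taus_from_driver <- function(taud, d, ba, bb) {
    i1 <- d %% 3 + 1
    i2 <- i1 %% 3 + 1
    ta <- solve_tau(fs_of(taud), Mv[[i1]])[, ba]
    tb <- solve_tau(fs_of(ta), Mv[[i2]])[, bb]
    out <- numeric(3)
    out[d] <- taud; out[i1] <- ta; out[i2] <- tb
    out
  }
  grid <- seq(-180, 180, length.out = grid_size + 1)
  drivers <- if (thorough) 1:3 else 1L
  cand <- list()
  for (d in drivers) for (ba in 1:2) for (bb in 1:2) {
    fa <- function(t) {
      v <- abs(residual_chain(t, d, ba, bb))
      v[!is.finite(v)] <- 1e6
      v
    }
    r <- residual_chain(grid, d, ba, bb)
    fin <- is.finite(r)
    add <- function(t, polish) {
      cand[[length(cand) + 1]] <<- c(t, d, ba, bb, polish)
    }
    exact <- which(fin & r == 0)
    for (k in exact) add(grid[k], 0)
    ## vectorised bisection over all sign-change brackets at once
    k <- which(fin[-length(fin)] & fin[-1] &
               r[-length(r)] * r[-1] < 0)
    if (length(k)) {
      lo <- grid[k]; hi <- grid[k + 1]
      flo <- r[k]
      for (it in 1:52) {
        mid <- (lo + hi) / 2
        fm <- residual_chain(mid, d, ba, bb)
        fm[!is.finite(fm)] <- 0   # treat as converged; verified later
        left <- flo * fm <= 0
        hi[left] <- mid[left]
        lo[!left] <- mid[!left]
        flo[!left] <- fm[!left]
      }
      for (t in (lo + hi) / 2) add(t, 0)
    }
    if (thorough) {
      ## branch-domain edges: a root may hide in the partial interval
      for (k in which(xor(fin[-length(fin)], fin[-1]))) {
        op <- stats::optimize(fa, c(grid[k], grid[k + 1]), tol = 1e-12)
        if (op$objective < 1e-8) add(op$minimum, 1)
      }
      ## tangent roots produce no sign change: refine local minima of |r|
      for (k in seq_len(grid_size + 1)) {
        if (!fin[k] || abs(r[k]) > 0.3) next
        left <- if (k > 1 && fin[k - 1]) abs(r[k - 1]) else Inf
        right <- if (k < grid_size + 1 && fin[k + 1]) abs(r[k + 1]) else Inf
        if (abs(r[k]) > left || abs(r[k]) > right) next
        op <- stats::optimize(fa, c(grid[max(1, k - 1)],
                                    grid[min(grid_size + 1, k + 1)]),
                              tol = 1e-12)
        if (op$objective < 1e-8) add(op$minimum, 1)
      }
    }
  }
  if (!length(cand)) return(empty)
  ## resolve every candidate to a full tau triple, then deduplicate before
  ## the (comparatively expensive) reconstruction step
  taus_all <- NULL
  polish_flag <- logical(0)
  for (cd in cand) {
    resid <- residual_chain(cd[1], cd[2], cd[3], cd[4])
    if (!is.finite(resid) || abs(resid) > 1e-6) next
    taus <- wrap_angle(taus_from_driver(cd[1], cd[2], cd[3], cd[4]))
    if (!is.null(taus_all) && nrow(taus_all)) {
      dup <- which(apply(taus_all, 1, function(z) {
        all(ang_dist(z, taus) < 1e-4)
      }))
      if (length(dup)) {
        polish_flag[dup] <- polish_flag[dup] & cd[5] == 1
        next
      }
    }
    taus_all <- rbind(taus_all, taus)
    polish_flag <- c(polish_flag, cd[5] == 1)
  }
  if (is.null(taus_all)) return(empty)
  sols <- list()
  pivtor <- NULL
  for (s in seq_len(nrow(taus_all))) {
    co <- reconstruct_ring(seq, segs, V, e, R, taus_all[s, ], pv)
    tmp <- new_conformation(seq, NULL, co, aux = NULL)
    tt <- measure_torsions(tmp)
    ## roots located only by |residual| minimisation (tangencies, domain
    ## edges) can sit slightly off; refine them against the exact gap
    if (polish_flag[s]) tt <- polish_pivots(tt, pv)
    conf <- build_from_torsions(seq, tt)
    if (!is_closed(conf, tol_bond = 1e-4, tol_angle = 1e-3)) next
    six <- as.numeric(t(tt[pv, c("phi", "psi")]))
    if (!is.null(pivtor) && nrow(pivtor) &&
        any(apply(pivtor, 1, function(z) all(ang_dist(z, six) < 1e-3)))) next
    sols[[length(sols) + 1]] <- conf
    pivtor <- rbind(pivtor, six)
  }
  if (is.null(pivtor)) pivtor <- matrix(numeric(), 0, 6)
  colnames(pivtor) <- c("phi1", "psi1", "phi2", "psi2", "phi3", "psi3")
  rownames(pivtor) <- NULL
  structure(list(solutions = sols, pivot_torsions = pivtor),
            class = "closure_solutions")
}

#' @export
print.closure_solutions <- function(x, ...) {
  cat("closure solution set:", length(x$solutions), "solution(s)\n")
  invisible(x)
}

## Assemble ring backbone coordinates from solved taus.
reconstruct_ring <- function(seq, segs, V, e, R, taus, pv) {
  n <- nrow(seq)
  co <- array(NA_real_, dim = c(n, length(.atom_slots), 3),
              dimnames = list(NULL, .atom_slots, c("x", "y", "z")))
  for (k in 1:3) {
    Rk <- rodrigues_matrix(e[k, ], taus[k]) %*% R[[k]]
    org <- V[k, ]
    for (nm in names(segs[[k]]$atoms)) {
      parts <- strsplit(nm, " ", fixed = TRUE)[[1]]
      res <- as.integer(parts[2])
      xyz <- org + as.numeric(Rk %*% segs[[k]]$atoms[[nm]])
      co[res, parts[1], ] <- xyz
    }
  }
  co
}

## Hydrogen-bond minimum schedule -------------------------------------------

#' Minimum internal hydrogen bonds required for a macrocycle length
#'
#' Two policies are exposed and deliberately not reconciled: the
#' length-dependent schedule (1 bond for 6-7 residues, 2 for 8-9, 3 for 10 or
#' more; the default) and a flat minimum of 2.
#'
#' @param n macrocycle length.
#' @param policy `"by_length"` or `"fixed2"`.
#' @return Integer minimum.
#' @export
min_hbonds_for_length <- function(n, policy = c("by_length", "fixed2")) {
  policy <- match.arg(policy)
  if (policy == "fixed2") return(2L)
  if (n <= 7) 1L else if (n <= 9) 2L else 3L
}

#' Acceptance policy for sampled cyclic backbones
#'
#' @param min_hbonds_policy hydrogen-bond minimum schedule, see
#'   [min_hbonds_for_length()].
#' @param min_hbonds explicit override of the minimum (NULL = use schedule).
#' @param rama_cutoff pivot Ramachandran pseudo-energy cutoff.
#' @param clash_distance backbone bump-check distance (Angstrom).
#' @param hbond_cutoff hydrogen-bond reporting cutoff (score units).
#' @param weights weight set used to rank closure solutions.
#' @param cis_probability probability of sampling a cis (omega = 0) peptide
#'   bond at proline and N-methylated positions (0 elsewhere).
#' @return A `backbone_acceptance_policy` list.
#' @export
backbone_acceptance_policy <- function(min_hbonds_policy = "by_length",
                                       min_hbonds = NULL,
                                       rama_cutoff = 2,
                                       clash_distance = 2.6,
                                       hbond_cutoff = -0.25,
                                       weights = "closure_selection",
                                       cis_probability = 0) {
  structure(list(min_hbonds_policy = min_hbonds_policy,
                 min_hbonds = min_hbonds, rama_cutoff = rama_cutoff,
                 clash_distance = clash_distance,
                 hbond_cutoff = hbond_cutoff, weights = weights,
                 cis_probability = cis_probability),
            class = "backbone_acceptance_policy")
}

## pivot layout: anchor excluded, pivots roughly equally spaced
default_pivots <- function(anchor, n) {
  sort(((anchor + c(1, floor(n / 2) + 1, n - 1) - 1) %% n) + 1)
}

#' Sample closed cyclic backbones
#'
#' Each attempt draws the non-pivot phi/psi from the flat-bottom
#' mirror-symmetric Ramachandran table, sets omegas to 180 (with optional cis
#' sampling at proline/N-methyl positions), solves the closure analytically,
#' filters solutions (backbone bump check, pivot Ramachandran check, minimum
#' internal hydrogen bonds) and keeps the lowest-energy passing solution
#' under the policy's weight set.  Fully deterministic for a fixed seed.
#'
#' @param seq a [macrocycle_sequence()].
#' @param n_attempts number of closure attempts.
#' @param rng_seed integer seed.
#' @param policy a [backbone_acceptance_policy()].
#' @param mirror draw the mirrored torsion stream: with the same seed and the
#'   mirrored sequence, yields the exact mirror ensemble.
#' @return List of accepted `cycpep_conformation`s with attribute `manifest`
#'   (data frame: attempt, energy, hbonds).  Zero acceptances is reported via
#'   an empty list, not an error.
#' @export
sample_cyclic_backbones <- function(seq, n_attempts, rng_seed,
                                    policy = backbone_acceptance_policy(),
                                    mirror = FALSE) {
  stopifnot(n_attempts >= 1)
  set.seed(rng_seed)
  n <- nrow(seq)
  minhb <- if (!is.null(policy$min_hbonds)) policy$min_hbonds else
    min_hbonds_for_length(n, policy$min_hbonds_policy)
  cis_ok <- seq$aa == "PRO" | seq$n_methyl
  out <- list()
  man <- list()
  for (att in seq_len(n_attempts)) {
    anchor <- sample.int(n, 1)
    pv <- default_pivots(anchor, n)
    phipsi <- sample_flat_symm(n)
    omega <- rep(180, n)
    flip <- cis_ok & stats::runif(n) < policy$cis_probability
    omega[flip] <- 0
    tor <- cbind(phi = phipsi[, 1], psi = phipsi[, 2], omega = omega)
    if (mirror) tor <- wrap_angle(-tor)
    sol <- solve_closure(closure_problem(seq, tor, pv, anchor),
                         grid_size = 360, thorough = FALSE)
    best <- NULL
    best_e <- Inf
    best_hb <- NA_integer_
    for (conf in sol$solutions) {
      if (!all(vapply(pv, function(i) {
        rama_prepro_check(conf, i, policy$rama_cutoff)
      }, logical(1)))) next
      if (!loop_bump_check(conf, policy$clash_distance)) next
      hb <- count_internal_hbonds(conf, policy$hbond_cutoff)
      if (hb < minhb) next
      eb <- score_conformation(conf, policy$weights,
                               hbond_cutoff = policy$hbond_cutoff)
      if (eb$total < best_e) {
        best <- conf; best_e <- eb$total; best_hb <- hb
      }
    }
    if (!is.null(best)) {
      out[[length(out) + 1]] <- best
      man[[length(man) + 1]] <- data.frame(attempt = att, energy = best_e,
                                           hbonds = best_hb)
    }
  }
  if (!length(out)) {
    message("no conformations accepted after ", n_attempts, " attempts")
  }
  attr(out, "manifest") <- if (length(man)) do.call(rbind, man) else
    data.frame(attempt = integer(), energy = numeric(), hbonds = integer())
  out
}
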