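## PAMPA apparent permeability -----------------------------------------------

#' A single PAMPA measurement
#'
#' @param C_A acceptor-well concentration at time t (any unit shared with
#'   `C_D`).
#' @param C_D donor-well concentration at time t.
#' @param t incubation time in seconds.
#' @param A filter area in cm^2 (no default: assay-plate specific).
#' @param V_D donor well volume in cm^3 (default 0.300 = 300 uL).
#' @param V_A acceptor well volume in cm^3 (default 0.250 = 250 uL).
#' @return A `pampa_measurement` list.
#' @export
pampa_measurement <- function(C_A, C_D, t, A, V_D = 0.300, V_A = 0.250) {
  stopifnot(V_D > 0, V_A > 0, A > 0, t > 0, C_A >= 0, C_D >= 0)
  structure(list(C_A = C_A, C_D = C_D, t = t, A = A, V_D = V_D, V_A = V_A),
            class = "pampa_measurement")
}

#' Equilibrium concentration by mass balance
#'
#' `Ce = (C_D * V_D + C_A * V_A) / (V_D + V_A)`.
#'
#' @param m a [pampa_measurement()].
#' @return Equilibrium concentration in the input concentration unit.
#' @export
equilibrium_conc <- function(m) {
  (m$C_D * m$V_D + m$C_A * m$V_A) / (m$V_D + m$V_A)
}

#' Apparent permeability (P_app)
#'
#' `P_app = -ln(1 - C_A / Ce) / (A * (1/V_D + 1/V_A) * t)` in cm/s, with the
#' single-denominator grouping fixed by dimensional analysis (cm^2 * cm^-3 *
#' s in the denominator gives cm/s).
#'
#' @param m a [pampa_measurement()].
#' @return A `permeability_result`: list with `C_e`, `P_app` (cm/s) and
#'   `class` (see [classify_permeability()]).
#' @export
papp <- function(m) {
  ce <- equilibrium_conc(m)
  if (m$C_A >= ce) {
    stop("acceptor concentration at/over equilibrium: P_app undefined")
  }
  p <- -log(1 - m$C_A / ce) / (m$A * (1 / m$V_D + 1 / m$V_A) * m$t)
  structure(list(C_e = ce, P_app = p, class = classify_permeability(p)),
            class = "permeability_result")
}

#' Classify an apparent permeability
#'
#' Thresholds (inclusive upward): below 1e-7 cm/s is below the detection
#' convention, at or above 1e-7 permeable, at or above 1e-6 significant, at
#' or above 1e-5 high.
#'
#' @param p P_app in cm/s (non-negative).
#' @return One of `"below_detection"`, `"permeable"`, `"significant"`,
#'   `"high"`.
#' @export
classify_permeability <- function(p) {
  stopifnot(all(is.finite(p)))
  if (any(p < 0)) stop("P_app must be non-negative")
  cut <- function(x) {
    if (x >= 1e-5) "high"
    else if (x >= 1e-6) "significant"
    else if (x >= 1e-7) "permeable"
    else "below_detection"
  }
  vapply(p, cut, character(1))
}

#' Compute P_app for a table of PAMPA measurements
#'
#' Input columns: `id`, `C_A`, `C_D`, `V_D`, `V_A`, `A`, `t` and optionally
#' `replicate`.  Returns per-row results plus per-id mean and standard
#' deviation over replicates.
#'
#' @param x data frame or path to a TSV/CSV file (delimiter inferred from
#'   the extension).
#' @param out optional output TSV path for the per-row results.
#' @return List with `rows` (per-measurement results) and `by_id`
#'   (id, n, mean_papp, sd_papp, class of the mean).
#' @export
papp_table <- function(x, out = NULL) {
  if (is.character(x)) {
    sep <- if (grepl("\\.csv$", x, ignore.case = TRUE)) "," else "\t"
    x <- utils::read.table(x, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  }
  need <- c("id", "C_A", "C_D", "A", "t")
  if (!all(need %in% names(x))) {
    stop("missing columns: ", paste(setdiff(need, names(x)), collapse = ", "))
  }
  if (is.null(x$V_D)) x$V_D <- 0.300
  if (is.null(x$V_A)) x$V_A <- 0.250
  rows <- x
  res <- lapply(seq_len(nrow(x)), function(i) {
    papp(pampa_measurement(x$C_A[i], x$C_D[i], x$t[i], x$A[i],
                           x$V_D[i], x$V_A[i]))
  })
  rows$C_e <- vapply(res, function(r) r$C_e, numeric(1))
  rows$P_app <- vapply(res, function(r) r$P_app, numeric(1))
  rows$class <- vapply(res, function(r) r$class, character(1))
  by_id <- do.call(rbind, lapply(split(rows, rows$id), function(g) {
    data.frame(id = g$id[1], n = nrow(g),
               mean_papp = mean(g$P_app),
               sd_papp = if (nrow(g) > 1) stats::sd(g$P_app) else NA_real_,
               class = classify_permeability(mean(g$P_app)),
               stringsAsFactors = FALSE)
  }))
  rownames(by_id) <- NULL
  if (!is.null(out)) {
    utils::write.table(rows, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(rows = rows, by_id = by_id)
}
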