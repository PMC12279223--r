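#' Inter-helical angle between two selections
#'
#' The axis of each helix is the dominant principal axis of its Calpha
#' coordinates, oriented N-terminus to C-terminus; the inter-helical angle
#' is the angle between the two unit axes, in [0, 180] degrees (0 =
#' parallel, 180 = antiparallel).  Before the fit the Calpha trace is
#' smoothed with a one-turn (four-residue) moving average, which removes
#' the helical wobble that otherwise tilts the principal axis by a degree
#' or two when the trace does not span whole turns.  A two-atom vector
#' mode (first-to-last Calpha) is available for comparison with tools that
#' define the axis from an atom pair.
#'
#' @param coords A [coord_ensemble()].
#' @param helix_a,helix_b Lists `list(chain =, residues =)` selecting at
#'   least 4 Calpha atoms each.
#' @param method `"principal_axis"` (default) or `"atom_vector"`.
#' @return Numeric vector of per-frame angles (degrees).
#' @export
interhelical_angle <- function(coords, helix_a, helix_b,
                               method = c("principal_axis", "atom_vector")) {
  method <- match.arg(method)
  stopifnot(inherits(coords, "coord_ensemble"))
  sel <- function(s) atom_select(coords, chain = s$chain,
                                 residues = s$residues, atom_names = "CA")
  ia <- sel(helix_a); ib <- sel(helix_b)
  if (length(ia) < 4 || length(ib) < 4)
    stop("each helix selection needs at least 4 Calpha atoms")
  nf <- dim(coords$coordinates)[1]
  axis_of <- function(xyz) {
    if (method == "atom_vector") {
      v <- xyz[nrow(xyz), ] - xyz[1, ]
    } else {
      n <- nrow(xyz)
      sm <- if (n >= 7) {
        t(vapply(seq_len(n - 3),
                 function(i) colMeans(xyz[i:(i + 3), , drop = FALSE]),
                 numeric(3)))
      } else xyz
      cc <- sweep(sm, 2, colMeans(sm))
      sv <- svd(cc, nu = 0, nv = 1)
      if (sv$d[1] < 1e-9) stop("degenerate helix selection")
      v <- sv$v[, 1]
      ## orient N -> C
      if (sum(v * (xyz[nrow(xyz), ] - xyz[1, ])) < 0) v <- -v
    }
    v / sqrt(sum(v^2))
  }
  vapply(seq_len(nf), function(f) {
    xa <- coords$coordinates[f, ia, , drop = TRUE]
    xb <- coords$coordinates[f, ib, , drop = TRUE]
    va <- axis_of(matrix(xa, ncol = 3))
    vb <- axis_of(matrix(xb, ncol = 3))
    acos(pmin(1, pmax(-1, sum(va * vb)))) * 180 / pi
  }, numeric(1))
}

#' Minimum inter-selection distance per frame
#'
#' Smallest heavy-atom pair distance between two selections in each frame.
#'
#' @param coords A [coord_ensemble()].
#' @param selection_a,selection_b Lists `list(chain =, residues =)`.
#' @return Numeric vector of per-frame distances (nm).
#' @export
min_distance <- function(coords, selection_a, selection_b) {
  stopifnot(inherits(coords, "coord_ensemble"))
  sel_a <- atom_select(coords, chain = selection_a$chain,
                       residues = selection_a$residues)
  sel_b <- atom_select(coords, chain = selection_b$chain,
                       residues = selection_b$residues)
  if (!length(sel_a) || !length(sel_b)) stop("empty selection")
  nf <- dim(coords$coordinates)[1]
  vapply(seq_len(nf), function(f) {
    xa <- matrix(coords$coordinates[f, sel_a, , drop = TRUE], ncol = 3)
    xb <- matrix(coords$coordinates[f, sel_b, , drop = TRUE], ncol = 3)
    .pair_min_dist(xa, xb)
  }, numeric(1))
}

#' Two-dimensional potential of mean force
#'
#' Histograms two order-parameter series (e.g. inter-chain contact count
#' and inter-helical angle), normalizes over occupied bins and converts to
#' free energy `F = -ln(P / P_max)` in kT, so the global minimum is exactly
#' 0.  Empty bins carry `NA` rather than an arbitrary cap: the data say
#' nothing about their height.
#'
#' @param x_series,y_series Equal-length numeric series.
#' @param x_breaks,y_breaks Bin edges; defaults cover the data with bin
#'   widths 2 (x, contact-count convention) and 10 (y, degrees).
#' @return An object of class `"pmf2d"`: list with `F` (kT), `counts`,
#'   `x_breaks`, `y_breaks`, `n_frames`.
#' @export
pmf2d <- function(x_series, y_series, x_breaks = NULL, y_breaks = NULL) {
  stopifnot(length(x_series) == length(y_series))
  if (!length(x_series)) stop("zero frames")
  auto_breaks <- function(v, w) {
    lo <- floor(min(v) / w) * w
    hi <- ceiling(max(v) / w) * w
    if (hi <= lo) hi <- lo + w
    seq(lo, hi, by = w)
  }
  if (is.null(x_breaks)) x_breaks <- auto_breaks(x_series, 2)
  if (is.null(y_breaks)) y_breaks <- auto_breaks(y_series, 10)
  ix <- findInterval(x_series, x_breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  iy <- findInterval(y_series, y_breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  counts <- matrix(0L, length(x_breaks) - 1, length(y_breaks) - 1)
  for (k in seq_along(ix))
    counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + 1L
  P <- counts / sum(counts)
  Fmat <- matrix(NA_real_, nrow(P), ncol(P))
  occ <- counts > 0
  Fmat[occ] <- -log(P[occ] / max(P))
  structure(list(F = Fmat, counts = counts,
                 x_breaks = x_breaks, y_breaks = y_breaks,
                 n_frames = length(x_series)),
            class = "pmf2d")
}

#' @export
print.pmf2d <- function(x, ...) {
  cat(sprintf(
    "2D PMF: %d x %d bins, %d frames, %d occupied; max barrier %.2f kT\n",
    nrow(x$F), ncol(x$F), x$n_frames, sum(x$counts > 0),
    max(x$F, na.rm = TRUE)))
  invisible(x)
}

#' Dimer association / dissociation events
#'
#' Hysteretic two-state segmentation of a per-frame contact-count series:
#' a bound dimer dissociates when the count drops below
#' `unbound_threshold`, and an unbound pair reassociates when the count
#' reaches `bound_threshold`.  The gap between the thresholds suppresses
#' spurious events from frames fluctuating near a single cutoff.  The
#' initial state is bound unless the first frame is already below
#' `unbound_threshold`.
#'
#' @param contact_counts Per-frame numeric series.
#' @param bound_threshold Count at or above which an unbound pair rebinds.
#' @param unbound_threshold Count below which a bound pair dissociates;
#'   must satisfy `bound_threshold > unbound_threshold >= 0`.
#' @return An object of class `"association_trace"`: list with per-frame
#'   logical `bound`, integer vectors `dissociation_frames` and
#'   `reassociation_frames`, and the thresholds used.
#' @export
association_events <- function(contact_counts, bound_threshold = 10,
                               unbound_threshold = 1) {
  if (!(bound_threshold > unbound_threshold && unbound_threshold >= 0))
    stop("need bound_threshold > unbound_threshold >= 0")
  n <- length(contact_counts)
  if (!n) stop("empty series")
  bound <- logical(n)
  state <- contact_counts[1] >= unbound_threshold
  diss <- integer(0); reas <- integer(0)
  for (f in seq_len(n)) {
    if (state && contact_counts[f] < unbound_threshold) {
      state <- FALSE
      diss <- c(diss, f)
    } else if (!state && contact_counts[f] >= bound_threshold) {
      state <- TRUE
      reas <- c(reas, f)
    }
    bound[f] <- state
  }
  structure(list(bound = bound, dissociation_frames = diss,
                 reassociation_frames = reas,
                 bound_threshold = bound_threshold,
                 unbound_threshold = unbound_threshold),
            class = "association_trace")
}

#' @export
print.association_trace <- function(x, ...) {
  cat(sprintf(
    "association trace: %d frames, %d dissociation(s), %d reassociation(s) (thresholds %g/%g)\n",
    length(x$bound), length(x$dissociation_frames),
    length(x$reassociation_frames), x$bound_threshold,
    x$unbound_threshold))
  invisible(x)
}
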