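#' Physicochemical scoring of sequences and elements
#'
#' Mean hydrophobicity H, hydrophobic moment muH, net charge z, the lipid
#' discriminant factor D = 0.944*muH + 0.33*z, sliding-window charge tracks
#' (NCPR/FCR), and a FoldIndex-style built-in disorder proxy.
#'
#' @name properties
NULL

#' Helical-wheel angle of the 3-11 helix, degrees per residue (3 turns per
#' 11 residues).
#' @export
WHEEL_DELTA <- 1080 / 11

.res_values <- function(residues, table, what) {
  r <- strsplit(toupper(residues), "")[[1]]
  miss <- setdiff(unique(r), names(table))
  if (length(miss))
    stop(what, ": no table entry for residue(s) ", paste(miss, collapse = ", "))
  unname(table[r])
}

#' Mean hydrophobicity of a residue string
#' @param residues character scalar of one-letter codes.
#' @param tables [residue_tables()].
#' @return H, the per-residue mean of the configured hydrophobicity scale.
#' @export
mean_hydrophobicity <- function(residues, tables = residue_tables()) {
  if (!nzchar(residues)) stop("empty residue string")
  mean(.res_values(residues, tables$hydrophobicity, "hydrophobicity"))
}

#' Mean hydrophobic moment of a residue string
#'
#' muH = (1/N) * |sum_i h_i * (cos(i*delta), sin(i*delta))|, i = 0..N-1,
#' the per-residue mean-moment convention of HELIQUEST.
#'
#' @param residues character scalar.
#' @param tables [residue_tables()].
#' @param delta_deg angular increment per residue. 100 degrees corresponds
#'   to the canonical alpha-helix used by the HELIQUEST equations; 1080/11
#'   (about 98.18) to the 3-11 wheel used for slot geometry.
#' @return muH >= 0 in scale units.
#' @export
hydrophobic_moment <- function(residues, tables = residue_tables(),
                               delta_deg = 100) {
  if (!nzchar(residues)) stop("empty residue string")
  if (delta_deg <= 0) stop("delta_deg must be positive")
  h <- .res_values(residues, tables$hydrophobicity, "hydrophobicity")
  ang <- (seq_along(h) - 1) * delta_deg * pi / 180
  sqrt(sum(h * cos(ang))^2 + sum(h * sin(ang))^2) / length(h)
}

#' Net charge of a residue string
#' @param residues character scalar.
#' @param tables [residue_tables()].
#' @return z in elementary charges (default table: #KR - #DE).
#' @export
net_charge <- function(residues, tables = residue_tables()) {
  if (!nzchar(residues)) stop("empty residue string")
  sum(.res_values(residues, tables$charge, "charge"))
}

#' Lipid discriminant factor
#'
#' D = 0.944*muH + 0.33*z, a composite separating lipid-binding from
#' non-binding amphipathic elements.
#' @param muH hydrophobic moment (>= 0).
#' @param z net charge.
#' @return D (dimensionless).
#' @export
discriminant_factor <- function(muH, z) {
  stopifnot(all(muH >= 0))
  0.944 * muH + 0.33 * z
}

#' Sliding-window charge track (NCPR and FCR)
#'
#' @param record `sequence_record` or plain residue string.
#' @param window window size in residues (default 10).
#' @param tables [residue_tables()].
#' @return data.frame with columns `start` (1-based window start), `ncpr`
#'   (net charge per residue, in [-1,1]) and `fcr` (fraction of charged
#'   residues, in [0,1]).
#' @export
windowed_charge <- function(record, window = 10L, tables = residue_tables()) {
  residues <- if (inherits(record, "sequence_record")) record$residues else record
  n <- nchar(residues)
  if (n < window) stop("sequence shorter than window")
  q <- .res_values(residues, tables$charge, "charge")
  cq <- cumsum(c(0, q))
  cc <- cumsum(c(0, as.numeric(q != 0)))
  starts <- seq_len(n - window + 1L)
  data.frame(start = starts,
             ncpr = (cq[starts + window] - cq[starts]) / window,
             fcr = (cc[starts + window] - cc[starts]) / window)
}

#' FoldIndex-style disorder proxy track
#'
#' Windowed 2.785*<H_KD,norm> - |<NCPR>| - 1.151 with Kyte-Doolittle
#' hydropathy rescaled to [0,1]; negative values indicate disorder. Also
#' returns a pseudo-disorder score clamp(0.5 - FI/2, 0, 1) on the [0,1]
#' scale of external disorder predictors. A built-in proxy for workflows
#' without an external disorder track; externally supplied tracks are
#' preferred when available.
#'
#' @param record `sequence_record` or residue string.
#' @param tables [residue_tables()].
#' @param window odd window size (default 51), clipped to sequence length.
#' @return data.frame with columns `position`, `foldindex`, `disorder`.
#' @export
foldindex_track <- function(record, tables = residue_tables(), window = 51L) {
  residues <- if (inherits(record, "sequence_record")) record$residues else record
  n <- nchar(residues)
  if (window %% 2L == 0L) stop("window must be odd")
  w <- min(window, if (n %% 2L == 1L) n else n - 1L)
  half <- (w - 1L) %/% 2L
  hkd <- (.res_values(residues, tables$kyte_doolittle, "kyte_doolittle") + 4.5) / 9
  q <- .res_values(residues, tables$charge, "charge")
  ch <- cumsum(c(0, hkd)); cq <- cumsum(c(0, q))
  pos <- seq_len(n)
  lo <- pmax(pos - half, 1L); hi <- pmin(pos + half, n)
  m <- hi - lo + 1L
  mh <- (ch[hi + 1L] - ch[lo]) / m
  ncpr <- abs((cq[hi + 1L] - cq[lo]) / m)
  fi <- 2.785 * mh - ncpr - 1.151
  data.frame(position = pos, foldindex = fi,
             disorder = pmin(pmax(0.5 - fi / 2, 0), 1))
}

#' Annotate detected elements with the full property set
#'
#' Fills H, muH (both the 100-degree HELIQUEST angle and the 3-11 wheel
#' angle), z, D and mean disorder for every element. D is computed from the
#' 100-degree moment by default.
#'
#' @param elements data.frame with `sequence_id`, `start`, `end` (and
#'   optionally the wheel-slot count from the detector).
#' @param record the `sequence_record` the elements belong to.
#' @param tables [residue_tables()].
#' @param disorder_source `"track"` (use the record's attached track),
#'   `"foldindex"` (built-in proxy), or `"none"`.
#' @param d_angle which moment feeds D: `"heliquest"` (100 degrees, default)
#'   or `"wheel"`.
#' @return the elements data.frame with property columns appended.
#' @export
annotate_elements <- function(elements, record, tables = residue_tables(),
                              disorder_source = c("track", "foldindex", "none"),
                              d_angle = c("heliquest", "wheel")) {
  disorder_source <- match.arg(disorder_source)
  d_angle <- match.arg(d_angle)
  n <- nchar(record$residues)
  if (nrow(elements) && (any(elements$start < 1) || any(elements$end > n)))
    stop("element out of sequence bounds for ", record$id)
  dis <- switch(disorder_source,
    track = {
      if (is.null(record$disorder_track))
        stop("no disorder track attached to ", record$id)
      record$disorder_track
    },
    foldindex = foldindex_track(record, tables)$disorder,
    none = NULL)
  m <- nrow(elements)
  H <- muH <- muHw <- z <- md <- numeric(m)
  for (i in seq_len(m)) {
    s <- substr(record$residues, elements$start[i], elements$end[i])
    H[i] <- mean_hydrophobicity(s, tables)
    muH[i] <- hydrophobic_moment(s, tables, 100)
    muHw[i] <- hydrophobic_moment(s, tables, WHEEL_DELTA)
    z[i] <- net_charge(s, tables)
    md[i] <- if (is.null(dis)) NA_real_
             else mean(dis[elements$start[i]:elements$end[i]])
  }
  elements$n_res <- if (m) elements$end - elements$start + 1L else integer(0)
  elements$H <- H
  elements$muH <- muH
  elements$muH_wheel <- muHw
  elements$z <- z
  elements$D <- discriminant_factor(if (d_angle == "heliquest") muH else muHw, z)
  elements$mean_disorder <- md
  elements
}

#' Fraction of basic residues (K, R) in a residue string
#' @param residues character scalar.
#' @return value in [0,1].
#' @export
basic_fraction <- function(residues) {
  r <- strsplit(toupper(residues), "")[[1]]
  mean(r %in% c("K", "R"))
}
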