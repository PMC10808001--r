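#' Amphipathic 3-11 helical element detection
#'
#' The detector mirrors helical-wheel analysis of apolipoprotein-like
#' repeats: a sequence is first segmented at helix breakers (proline,
#' continuous glycines, runs of >= 4 polar/negative residues), each segment
#' is scanned with a 7-residue window tested for an aligned amphipathic
#' interface, and valid overlapping-or-adjacent windows are stitched into
#' maximal elements. Elements are finally required to occupy between 3 and
#' 5 of the 11 wheel slots with hydrophobic residues.
#'
#' @name amphipathy
NULL

#' Default detection parameters
#'
#' @param G_run_min minimum glycine run length treated as a break
#'   ("continuous glycines"; a single G is allowed). Default 2.
#' @param polar_run_min minimum polar/negative run length treated as a
#'   break ("over four (including four)"). Default 4.
#' @param window amphipathicity test window, residues. Default 7.
#' @param face_min,face_max allowed count of hydrophobic-face residues per
#'   window. Defaults 2 and 5.
#' @param arc_max maximal wheel arc (degrees) that must contain all face
#'   residues of a window. Default 180.
#' @param muH_min minimal window hydrophobic moment at the wheel angle.
#'   Default 0.2 (scale units).
#' @param delta_deg angular step per residue used for window geometry and
#'   the window moment. Default the 3-11 wheel angle 1080/11.
#' @param slot_min,slot_max element-level bounds on distinct hydrophobic
#'   wheel slots; `slot_filter` switches the filter on/off. Defaults 3, 5,
#'   TRUE.
#' @return list of parameters.
#' @export
detect_params <- function(G_run_min = 2L, polar_run_min = 4L, window = 7L,
                          face_min = 2L, face_max = 5L, arc_max = 180,
                          muH_min = 0.2, delta_deg = WHEEL_DELTA,
                          slot_min = 3L, slot_max = 5L, slot_filter = TRUE) {
  list(G_run_min = G_run_min, polar_run_min = polar_run_min, window = window,
       face_min = face_min, face_max = face_max, arc_max = arc_max,
       muH_min = muH_min, delta_deg = delta_deg,
       slot_min = slot_min, slot_max = slot_max, slot_filter = slot_filter)
}

#' Positions of helix-break residues in a sequence
#'
#' @param residues character scalar.
#' @param tables [residue_tables()].
#' @param params [detect_params()].
#' @return integer vector of 1-based break positions.
#' @export
break_positions <- function(residues, tables = residue_tables(),
                            params = detect_params()) {
  r <- strsplit(toupper(residues), "")[[1]]
  n <- length(r)
  brk <- r == "P"
  # runs of G and of polar/negative residues; whole run marked when long enough
  mark_runs <- function(is_member, min_len) {
    out <- logical(n)
    rl <- rle(is_member)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    long <- rl$values & rl$lengths >= min_len
    for (k in which(long)) out[starts[k]:ends[k]] <- TRUE
    out
  }
  brk <- brk | mark_runs(r == "G", params$G_run_min)
  brk <- brk | mark_runs(r %in% tables$polar_set, params$polar_run_min)
  which(brk)
}

#' Segment a sequence at helix breakers
#'
#' Break-causing residues are excluded from all segments; segments plus
#' break regions partition the input exactly.
#'
#' @param record `sequence_record` or residue string.
#' @param tables [residue_tables()].
#' @param params [detect_params()].
#' @return data.frame with `start`, `end` (1-based inclusive), `residues`.
#' @export
segment_sequence <- function(record, tables = residue_tables(),
                             params = detect_params()) {
  residues <- if (inherits(record, "sequence_record")) record$residues else record
  n <- nchar(residues)
  empty <- data.frame(start = integer(0), end = integer(0),
                      residues = character(0), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  ok <- rep(TRUE, n)
  ok[break_positions(residues, tables, params)] <- FALSE
  if (!any(ok)) return(empty)
  rl <- rle(ok)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  keep <- rl$values
  data.frame(start = starts[keep], end = ends[keep],
             residues = substring(residues, starts[keep], ends[keep]),
             stringsAsFactors = FALSE)
}

#' Helical-wheel slot of a residue offset
#'
#' On the 11-slot wheel of the 3-11 helix, residue offset i (0-based within
#' an element) projects to slot (3*i) mod 11.
#'
#' @param offset non-negative integer offset(s).
#' @return integer slot(s) in 0..10.
#' @export
wheel_slot <- function(offset) {
  if (any(offset < 0)) stop("offset must be non-negative")
  (3L * as.integer(offset)) %% 11L
}

# smallest circular arc (degrees) containing all angles; 0 for <= 1 point
.min_enclosing_arc <- function(angles_deg) {
  k <- length(angles_deg)
  if (k <= 1L) return(0)
  a <- sort(angles_deg %% 360)
  gaps <- diff(c(a, a[1] + 360))
  360 - max(gaps)
}

#' Test a 7-residue window for amphipathicity
#'
#' A window passes when (a) its hydrophobic-face residue count is within
#' `face_min..face_max`, (b) all face residues fall within a wheel arc of
#' at most `arc_max` degrees, and (c) its hydrophobic moment at the wheel
#' angle is at least `muH_min`.
#'
#' @param window_residues residue string of length `params$window`.
#' @param tables [residue_tables()].
#' @param params [detect_params()].
#' @return logical; attribute `diagnostics` lists the per-criterion results
#'   (`face_count`, `arc`, `muH`, and which criteria passed).
#' @export
window_is_amphipathic <- function(window_residues, tables = residue_tables(),
                                  params = detect_params()) {
  r <- strsplit(toupper(window_residues), "")[[1]]
  if (length(r) != params$window)
    stop("window must have exactly ", params$window, " residues")
  face <- which(r %in% tables$face_set)
  nface <- length(face)
  ok_count <- nface >= params$face_min && nface <= params$face_max
  arc <- .min_enclosing_arc((face - 1) * params$delta_deg)
  ok_arc <- arc <= params$arc_max
  muH <- hydrophobic_moment(window_residues, tables, params$delta_deg)
  ok_muH <- muH >= params$muH_min
  structure(ok_count && ok_arc && ok_muH,
            diagnostics = list(face_count = nface, face_count_ok = ok_count,
                               arc = arc, arc_ok = ok_arc,
                               muH = muH, muH_ok = ok_muH))
}

#' Distinct hydrophobic wheel slots of an element
#'
#' @param residues the element's residue string.
#' @param tables [residue_tables()].
#' @return sorted integer vector of slots (0..10) occupied by face residues,
#'   offsets counted from the element start.
#' @export
hydrophobic_slots <- function(residues, tables = residue_tables()) {
  r <- strsplit(toupper(residues), "")[[1]]
  face <- which(r %in% tables$face_set)
  sort(unique(wheel_slot(face - 1L)))
}

#' Detect amphipathic 3-11 helical elements in a sequence
#'
#' Within each helix-break-free segment a 7-residue window slides left to
#' right; valid windows whose intervals overlap or abut are merged into
#' maximal elements, which are then kept only when their distinct
#' hydrophobic wheel-slot count lies within `slot_min..slot_max` (when the
#' filter is on). Detection is fully deterministic.
#'
#' @param record `sequence_record` or residue string.
#' @param tables [residue_tables()].
#' @param params [detect_params()].
#' @return data.frame of elements sorted by `start`: `sequence_id`, `start`,
#'   `end` (1-based inclusive), `n_res`, `n_hydro_slots`, `residues`.
#' @export
detect_elements <- function(record, tables = residue_tables(),
                            params = detect_params()) {
  residues <- if (inherits(record, "sequence_record")) record$residues else record
  id <- if (inherits(record, "sequence_record")) record$id else NA_character_
  segs <- segment_sequence(residues, tables, params)
  w <- params$window
  out <- list()
  for (si in seq_len(nrow(segs))) {
    seg <- segs[si, ]
    len <- seg$end - seg$start + 1L
    if (len < w) next
    valid_starts <- integer(0)
    for (off in 0:(len - w)) {
      win <- substr(seg$residues, off + 1L, off + w)
      if (isTRUE(window_is_amphipathic(win, tables, params)[1]))
        valid_starts <- c(valid_starts, seg$start + off)
    }
    if (!length(valid_starts)) next
    # merge overlapping or abutting window intervals [s, s+w-1]
    s0 <- valid_starts[1]; e0 <- valid_starts[1] + w - 1L
    for (s in valid_starts[-1]) {
      if (s <= e0 + 1L) e0 <- max(e0, s + w - 1L)
      else { out[[length(out) + 1L]] <- c(s0, e0); s0 <- s; e0 <- s + w - 1L }
    }
    out[[length(out) + 1L]] <- c(s0, e0)
  }
  if (!length(out))
    return(data.frame(sequence_id = character(0), start = integer(0),
                      end = integer(0), n_res = integer(0),
                      n_hydro_slots = integer(0), residues = character(0),
                      stringsAsFactors = FALSE))
  iv <- do.call(rbind, out)
  el <- data.frame(sequence_id = id, start = iv[, 1], end = iv[, 2],
                   stringsAsFactors = FALSE)
  el$n_res <- el$end - el$start + 1L
  el$residues <- substring(residues, el$start, el$end)
  el$n_hydro_slots <- vapply(el$residues,
                             function(s) length(hydrophobic_slots(s, tables)),
                             integer(1), USE.NAMES = FALSE)
  if (isTRUE(params$slot_filter))
    el <- el[el$n_hydro_slots >= params$slot_min &
             el$n_hydro_slots <= params$slot_max, , drop = FALSE]
  el <- el[order(el$start), c("sequence_id", "start", "end", "n_res",
                              "n_hydro_slots", "residues")]
  rownames(el) <- NULL
  el
}
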