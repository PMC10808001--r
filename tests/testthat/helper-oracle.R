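# Independent brute-force oracles used to cross-check the detector and the
# rank statistics. These deliberately re-derive everything from first
# principles (regex segmentation, exhaustive arc enumeration, direct vector
# sums) rather than calling the package's internal helpers.

oracle_moment <- function(residues, scale, delta_deg) {
  r <- strsplit(residues, "")[[1]]
  h <- scale[r]
  x <- 0; y <- 0
  for (i in seq_along(h)) {
    a <- (i - 1) * delta_deg * pi / 180
    x <- x + h[i] * cos(a)
    y <- y + h[i] * sin(a)
  }
  unname(sqrt(x^2 + y^2) / length(h))
}

# break mask by direct regex-style scanning
oracle_break_mask <- function(residues, polar_set, g_min = 2L, p_min = 4L) {
  r <- strsplit(residues, "")[[1]]
  n <- length(r)
  mask <- r == "P"
  run_members <- function(memb, minlen) {
    out <- logical(n)
    i <- 1L
    while (i <= n) {
      if (memb[i]) {
        j <- i
        while (j < n && memb[j + 1L]) j <- j + 1L
        if (j - i + 1L >= minlen) out[i:j] <- TRUE
        i <- j + 1L
      } else i <- i + 1L
    }
    out
  }
  mask | run_members(r == "G", g_min) | run_members(r %in% polar_set, p_min)
}

# window validity re-derived: face count, arc by exhaustive rotation scan,
# moment by direct sum
oracle_window_valid <- function(win, tables, params) {
  r <- strsplit(win, "")[[1]]
  face <- which(r %in% tables$face_set)
  nf <- length(face)
  if (nf < params$face_min || nf > params$face_max) return(FALSE)
  if (nf >= 2) {
    ang <- ((face - 1) * params$delta_deg) %% 360
    fits <- FALSE
    for (a0 in ang) {  # some face residue starts the minimal arc
      rel <- (ang - a0) %% 360
      if (max(rel) <= params$arc_max) { fits <- TRUE; break }
    }
    if (!fits) return(FALSE)
  }
  mu <- oracle_moment(win, tables$hydrophobicity, params$delta_deg)
  isTRUE(mu >= params$muH_min)
}

# full detector oracle: enumerate windows, union intervals, slot filter
oracle_detect <- function(residues, tables, params) {
  n <- nchar(residues)
  w <- params$window
  mask <- oracle_break_mask(residues, tables$polar_set,
                            params$G_run_min, params$polar_run_min)
  valid <- integer(0)
  if (n >= w) {
    for (s in 1:(n - w + 1)) {
      if (any(mask[s:(s + w - 1)])) next
      if (oracle_window_valid(substr(residues, s, s + w - 1), tables, params))
        valid <- c(valid, s)
    }
  }
  if (!length(valid)) return(data.frame(start = integer(0), end = integer(0)))
  covered <- logical(n)
  for (s in valid) covered[s:(s + w - 1)] <- TRUE
  rl <- rle(covered)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  iv <- data.frame(start = starts[rl$values], end = ends[rl$values])
  keep <- logical(nrow(iv))
  for (k in seq_len(nrow(iv))) {
    r <- strsplit(substr(residues, iv$start[k], iv$end[k]), "")[[1]]
    face <- which(r %in% tables$face_set)
    slots <- unique((3L * (face - 1L)) %% 11L)
    keep[k] <- !params$slot_filter ||
      (length(slots) >= params$slot_min && length(slots) <= params$slot_max)
  }
  iv[keep, , drop = FALSE]
}

# random test sequences over the full alphabet
random_sequence <- function(n, freq = NULL) {
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  paste(sample(aa, n, replace = TRUE, prob = freq), collapse = "")
}
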