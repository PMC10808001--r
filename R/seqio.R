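#' Sequence, score-track and element-table input/output
#'
#' Internal coordinates are 1-based inclusive throughout (matching residue
#' numbering in construct descriptions such as "residues 39-238"); BED output
#' converts to 0-based half-open intervals.
#'
#' @name seqio
NULL

new_sequence_record <- function(id, residues, label = NA_character_,
                                disorder_track = NULL) {
  residues <- toupper(residues)
  bad <- which(!strsplit(residues, "")[[1]] %in% AA20)
  if (length(bad))
    stop(sprintf("record '%s': non-canonical residue '%s' at position %d",
                 id, substr(residues, bad[1], bad[1]), bad[1]))
  if (!is.null(disorder_track)) {
    if (length(disorder_track) != nchar(residues))
      stop(sprintf("record '%s': disorder track length %d != sequence length %d",
                   id, length(disorder_track), nchar(residues)))
    if (any(disorder_track < 0 | disorder_track > 1))
      stop(sprintf("record '%s': disorder scores outside [0,1]", id))
  }
  structure(list(id = id, residues = residues, label = label,
                 disorder_track = disorder_track),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence_record> %s (%d aa%s%s)\n", x$id, nchar(x$residues),
              if (!is.na(x$label)) paste0(", ", x$label) else "",
              if (!is.null(x$disorder_track)) ", disorder track" else ""))
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file (wrapped or single-line records).
#' @param noncanonical policy for residues outside the 20-letter alphabet:
#'   `"reject"` (default, error naming record and position) or `"map_to_X"`
#'   is not offered -- non-canonical letters other than X are always
#'   rejected; `"drop"` removes whole offending records with a warning.
#' @return list of `sequence_record` objects (id, residues uppercased).
#' @export
read_fasta <- function(path, noncanonical = c("reject", "drop")) {
  noncanonical <- match.arg(noncanonical)
  if (!file.exists(path)) stop("file not found: ", path)
  # Biostrings silently drops characters outside its AA alphabet; trap its
  # warning and locate the offending record/position ourselves
  invalid <- FALSE
  aaset <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter", conditionMessage(w))) {
        invalid <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (invalid) {
    lines <- readLines(path)
    rec <- NA_character_; pos <- 0L
    for (ln in lines) {
      if (startsWith(ln, ">")) { rec <- sub("\\s.*$", "", substring(ln, 2)); pos <- 0L; next }
      ch <- strsplit(ln, "")[[1]]
      bad <- which(!toupper(ch) %in% c(Biostrings::AA_ALPHABET, letters))
      if (length(bad))
        stop(sprintf("record '%s': invalid character '%s' at position %d",
                     rec, ch[bad[1]], pos + bad[1]))
      pos <- pos + length(ch)
    }
    stop("invalid sequence characters in ", path)
  }
  if (length(aaset) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(aaset))
  out <- vector("list", length(aaset))
  keep <- logical(length(aaset))
  for (i in seq_along(aaset)) {
    res <- tryCatch(new_sequence_record(ids[i], as.character(aaset[[i]])),
                    error = identity)
    if (inherits(res, "error")) {
      if (noncanonical == "reject") stop(conditionMessage(res))
      warning("dropping ", conditionMessage(res))
    } else {
      out[[i]] <- res
      keep[i] <- TRUE
    }
  }
  out[keep]
}

#' Write sequence records to FASTA
#' @param records list of `sequence_record`.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(paste0(">", r$id), con)
    s <- r$residues
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read per-residue score tracks from TSV
#'
#' Expects columns `id`, `position` (1-based), `score`. Used to ingest
#' externally computed disorder scores (e.g. IUPred-style long-mode output).
#'
#' @param path TSV file.
#' @param expected_ids optional character vector; ids absent from it error.
#' @param contiguous require positions 1..n without gaps (default TRUE).
#' @param score_policy `"error"` (default) rejects scores outside [0,1];
#'   `"clamp"` clamps with a warning.
#' @return named list of score tracks; each a list(sequence_id, positions,
#'   scores).
#' @export
read_score_track <- function(path, expected_ids = NULL, contiguous = TRUE,
                             score_policy = c("error", "clamp")) {
  score_policy <- match.arg(score_policy)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("id", "position", "score")
  if (!all(need %in% names(d)))
    stop("score track needs columns id, position, score")
  if (!is.null(expected_ids)) {
    extra <- setdiff(unique(d$id), expected_ids)
    if (length(extra)) stop("unexpected ids in score track: ",
                            paste(extra, collapse = ", "))
  }
  if (any(d$score < 0 | d$score > 1)) {
    if (score_policy == "error") stop("scores outside [0,1] in ", path)
    warning("clamping scores outside [0,1]")
    d$score <- pmin(pmax(d$score, 0), 1)
  }
  tracks <- lapply(split(d, d$id), function(g) {
    g <- g[order(g$position), ]
    if (any(diff(g$position) <= 0))
      stop("positions not strictly increasing for id ", g$id[1])
    if (contiguous && !identical(g$position, seq_len(nrow(g))))
      stop("positions not 1-based contiguous for id ", g$id[1])
    list(sequence_id = g$id[1], positions = g$position, scores = g$score)
  })
  tracks
}

#' Attach a disorder track to a sequence record
#' @param record `sequence_record`.
#' @param track score track from [read_score_track()].
#' @return the record with `disorder_track` set.
#' @export
attach_track <- function(record, track) {
  if (length(track$scores) != nchar(record$residues))
    stop(sprintf("track length %d != sequence length %d for '%s'",
                 length(track$scores), nchar(record$residues), record$id))
  record$disorder_track <- track$scores
  record
}

#' Read localization labels from TSV (columns id, label)
#' @param path TSV file.
#' @return named character vector id -> label.
#' @export
read_labels <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("id", "label") %in% names(d)))
    stop("label table needs columns id, label")
  stats::setNames(d$label, d$id)
}

element_columns <- c("sequence_id", "start", "end", "n_res", "n_hydro_slots",
                     "H", "muH", "muH_wheel", "z", "D", "mean_disorder")

#' Write detected elements as TSV or BED
#'
#' TSV uses 1-based inclusive `start`/`end` plus all property columns; BED
#' uses 0-based half-open coordinates with the discriminant factor D (scaled
#' by `bed_score_scale` and clamped to 0..1000) in the score column.
#'
#' @param elements data.frame of annotated elements.
#' @param path output file.
#' @param dialect `"tsv"` or `"bed"`.
#' @param bed_score_scale multiplier applied to D for the BED score column.
#' @export
write_elements <- function(elements, path, dialect = c("tsv", "bed"),
                           bed_score_scale = 100) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# helix311 %s elements",
                       as.character(utils::packageVersion("helix311"))), con)
    cols <- intersect(element_columns, names(elements))
    if (nrow(elements) == 0 && length(cols) == 0) cols <- element_columns
    utils::write.table(
      if (nrow(elements)) elements[, cols, drop = FALSE]
      else stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols),
      con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    bed <- if (nrow(elements)) {
      data.frame(chrom = elements$sequence_id,
                 chromStart = elements$start - 1L,
                 chromEnd = elements$end,
                 name = sprintf("%s_%d_%d", elements$sequence_id,
                                elements$start, elements$end),
                 score = pmin(pmax(round(elements$D * bed_score_scale), 0), 1000),
                 strand = ".")
    } else data.frame()
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read an element TSV written by [write_elements()]
#' @param path TSV file.
#' @return data.frame of elements.
#' @export
read_elements <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}
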