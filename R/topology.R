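#' Declare one segment of a rigid/flexible chain architecture
#'
#' @param kind `"rigid"` or `"flexible"`.
#' @param start,end Inclusive residue range in chain numbering.
#' @param label Free-text label (e.g. `"SR3-6"`, `"hinge"`, `"SR78"`, `"CT"`).
#' @param template For rigid segments, a `bead_model` with exactly one bead
#'   per residue of the range. Flexible segments carry no template.
#' @return An object of class `segment`.
#' @export
segment <- function(kind = c("rigid", "flexible"), start, end, label = "",
                    template = NULL) {
  kind <- match.arg(kind)
  start <- as.integer(start); end <- as.integer(end)
  if (end < start) stop("segment end before start: ", label)
  if (kind == "flexible" && !is.null(template))
    stop("flexible segments carry no template: ", label)
  if (kind == "rigid" && !is.null(template)) {
    if (!inherits(template, "bead_model")) stop("template must be a bead_model")
    if (n_beads(template) != end - start + 1L)
      stop(sprintf("template of '%s' has %d beads for %d residues",
                   label, n_beads(template), end - start + 1L))
  }
  structure(list(kind = kind, start = start, end = end, label = label,
                 template = template), class = "segment")
}

segment_length <- function(seg) seg$end - seg$start + 1L

#' Build and validate a rigid/flexible segment topology
#'
#' Segments must tile a contiguous, ascending residue range with no overlaps
#' or gaps. Adjacent flexible segments are merged into one (a single linker);
#' at least one rigid segment is required.
#'
#' @param segments List of [segment()] objects, in chain order.
#' @param protein_label Free-text label for the chain.
#' @return An object of class `segment_topology` with elements `segments`,
#'   `first_residue` and `protein_label`.
#' @export
build_topology <- function(segments, protein_label = "") {
  if (!length(segments)) stop("at least one segment required")
  starts <- vapply(segments, `[[`, 0L, "start")
  if (is.unsorted(starts, strictly = TRUE))
    stop("segments must be in ascending residue order")
  for (i in seq_along(segments)[-1L]) {
    prev <- segments[[i - 1L]]; cur <- segments[[i]]
    if (cur$start != prev$end + 1L)
      stop(sprintf(
        "segments '%s' [%d,%d] and '%s' [%d,%d] are not contiguous",
        prev$label, prev$start, prev$end, cur$label, cur$start, cur$end))
  }
  # merge runs of adjacent flexible segments into one linker
  merged <- list(segments[[1L]])
  for (i in seq_along(segments)[-1L]) {
    cur <- segments[[i]]
    last <- merged[[length(merged)]]
    if (cur$kind == "flexible" && last$kind == "flexible") {
      merged[[length(merged)]] <- segment(
        "flexible", last$start, cur$end,
        label = paste(last$label, cur$label, sep = "+"))
      message(sprintf("merged adjacent flexible segments '%s' and '%s'",
                      last$label, cur$label))
    } else merged <- c(merged, list(cur))
  }
  kinds <- vapply(merged, `[[`, "", "kind")
  if (!any(kinds == "rigid")) stop("topology needs at least one rigid segment")
  structure(
    list(segments = merged, first_residue = merged[[1L]]$start,
         protein_label = protein_label),
    class = "segment_topology")
}

#' @export
print.segment_topology <- function(x, ...) {
  cat(sprintf("<segment_topology> %s: %d residues (%d..%d), hinge/linker total %d\n",
              if (nzchar(x$protein_label)) x$protein_label else "(unnamed)",
              topology_length(x), x$first_residue,
              x$segments[[length(x$segments)]]$end, flexible_length(x)))
  for (s in x$segments)
    cat(sprintf("  %-10s %-8s %5d..%-5d (%d residues)%s\n", s$label, s$kind,
                s$start, s$end, segment_length(s),
                if (!is.null(s$template)) " [template]" else ""))
  invisible(x)
}

#' Total residue count of a topology
#' @param topology A `segment_topology`.
#' @export
topology_length <- function(topology)
  sum(vapply(topology$segments, segment_length, 0L))

#' Total flexible (linker) residue count of a topology
#' @param topology A `segment_topology`.
#' @export
flexible_length <- function(topology) {
  flex <- Filter(function(s) s$kind == "flexible", topology$segments)
  if (!length(flex)) return(0L)
  sum(vapply(flex, segment_length, 0L))
}

rigid_segments <- function(topology)
  which(vapply(topology$segments, `[[`, "", "kind") == "rigid")

# 0-based offsets: bead indices (1-based) covered by each segment.
segment_bead_indices <- function(topology) {
  lens <- vapply(topology$segments, segment_length, 0L)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  Map(seq.int, starts, ends)
}

#' Write a topology as a human-editable config table
#'
#' Tab-separated columns `label`, `kind`, `start`, `end`, `template`; rigid
#' templates are written as C-alpha PDB files next to the config (or `-` when
#' absent).
#'
#' @param topology A `segment_topology`.
#' @param path Output config path; templates go to `<path>_<label>.pdb`.
#' @param write_templates Write rigid templates as PDB files (default TRUE).
#' @export
write_topology_config <- function(topology, path, write_templates = TRUE) {
  rows <- lapply(topology$segments, function(s) {
    tpl <- "-"
    if (!is.null(s$template) && write_templates) {
      tpl <- paste0(path, "_", gsub("[^A-Za-z0-9]+", "_", s$label), ".pdb")
      write_pdb_ca(s$template, tpl)
    }
    data.frame(label = s$label, kind = s$kind, start = s$start, end = s$end,
               template = tpl)
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# topology: %s", topology$protein_label), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a topology config written by [write_topology_config()]
#' @param path Config file path.
#' @return A validated `segment_topology`.
#' @export
read_topology_config <- function(path) {
  lines <- readLines(path)
  label_line <- grep("^# topology:", lines, value = TRUE)
  protein <- if (length(label_line))
    trimws(sub("^# topology:", "", label_line[1L])) else ""
  df <- utils::read.table(text = lines[!startsWith(lines, "#")],
                          header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "integer",
                                         "integer", "character"))
  segs <- lapply(seq_len(nrow(df)), function(i) {
    tpl <- NULL
    if (df$kind[i] == "rigid" && df$template[i] != "-" &&
        file.exists(df$template[i]))
      tpl <- load_pdb_as_beads(df$template[i])
    segment(df$kind[i], df$start[i], df$end[i], df$label[i], tpl)
  })
  build_topology(segs, protein_label = protein)
}
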