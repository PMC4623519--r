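#' Chain topology for a coarse-grained bead model
#'
#' One bead per residue. The chain is partitioned into named, ordered,
#' non-overlapping segments (1-based inclusive ranges) covering every bead.
#' Helical segments are those whose label matches `H<number>` (H1..H4 in the
#' four-helix-bundle presets); non-helical labels such as `hinge`, `tail`,
#' `nterm` or `loop*` mark connectors and disordered regions.
#'
#' @param segments data.frame with columns `label`, `start`, `end`
#'   (1-based inclusive residue ranges).
#' @param bead_mass bead mass, Da. Default 110, the average amino-acid
#'   residue mass, which also makes one reduced time unit ~50 fs.
#' @param bond_length covalent virtual-bond length between consecutive
#'   beads, Angstrom.
#' @param hard_core_diameter excluded-volume diameter for non-bonded pairs,
#'   Angstrom.
#' @return an object of class `chain_topology`.
#' @seealso [topology_mini_bundle()], [topology_apoe()]
#' @export
chain_topology <- function(segments, bead_mass = 110, bond_length = 3.8,
                           hard_core_diameter = 4.0) {
  stopifnot(is.data.frame(segments),
            all(c("label", "start", "end") %in% names(segments)))
  segments <- data.frame(label = as.character(segments$label),
                         start = as.integer(segments$start),
                         end = as.integer(segments$end),
                         stringsAsFactors = FALSE)
  if (any(segments$start > segments$end)) stop("segment start must be <= end")
  if (anyDuplicated(segments$label)) stop("segment labels must be unique")
  o <- order(segments$start)
  segments <- segments[o, , drop = FALSE]
  if (segments$start[1L] != 1L) stop("segments must start at residue 1")
  if (nrow(segments) > 1L &&
      any(segments$start[-1L] != segments$end[-nrow(segments)] + 1L)) {
    stop("segments must be contiguous and non-overlapping (cover 1..n_beads)")
  }
  n_beads <- segments$end[nrow(segments)]
  if (!is.numeric(bead_mass) || bead_mass <= 0) stop("bead_mass must be > 0")
  if (!is.numeric(bond_length) || bond_length <= 0) stop("bond_length must be > 0")
  if (!is.numeric(hard_core_diameter) || hard_core_diameter <= 0) {
    stop("hard_core_diameter must be > 0")
  }
  structure(list(n_beads = n_beads, segment_map = segments,
                 bead_mass = bead_mass, bond_length = bond_length,
                 hard_core_diameter = hard_core_diameter),
            class = "chain_topology")
}

#' @export
print.chain_topology <- function(x, ...) {
  cat("<chain_topology> ", x$n_beads, " beads, ",
      nrow(x$segment_map), " segments\n", sep = "")
  cat(paste0("  ", format(x$segment_map$label, width = 6), " ",
             x$segment_map$start, "-", x$segment_map$end, collapse = "\n"), "\n")
  cat("  mass ", x$bead_mass, " Da, bond ", x$bond_length,
      " A, hard core ", x$hard_core_diameter, " A\n", sep = "")
  invisible(x)
}

#' Desk-scale four-helix-bundle topology
#'
#' The default synthetic system: four helices of `helix_length` beads each,
#' a hinge and a flexible C-terminal tail, mirroring the apolipoprotein E
#' segment layout at reduced size (56 beads with the defaults).
#'
#' @param helix_length beads per helix (>= 4 so a helical turn can form).
#' @param hinge_length,tail_length beads in the hinge / tail segments.
#' @param ... passed on to [chain_topology()].
#' @return a `chain_topology`.
#' @export
topology_mini_bundle <- function(helix_length = 10, hinge_length = 6,
                                 tail_length = 10, ...) {
  if (helix_length < 4) stop("segment too short to form a helix (< 4 beads)")
  h <- helix_length
  starts <- cumsum(c(1, h, h, h, h, hinge_length)) # first 5 are segment starts
  segments <- data.frame(
    label = c("H1", "H2", "H3", "H4", "hinge", "tail"),
    start = c(starts[1:4], starts[5], starts[6]),
    end = c(starts[2:5] - 1L, starts[6] - 1L, starts[6] + tail_length - 1L))
  chain_topology(segments, ...)
}

#' Full-length apolipoprotein E segment layout
#'
#' The 299-residue preset with the canonical segment boundaries: H1 24-41,
#' H2 55-80, H3 90-125, H4 131-165, hinge 166-205, C-terminal tail 206-299,
#' plus the leading N-terminal stretch and inter-helix loops. Retained as a
#' preset for full-scale runs; the desk-scale tests use
#' [topology_mini_bundle()].
#'
#' @param ... passed on to [chain_topology()].
#' @return a `chain_topology`.
#' @export
topology_apoe <- function(...) {
  segments <- data.frame(
    label = c("nterm", "H1", "loop1", "H2", "loop2", "H3", "loop3", "H4",
              "hinge", "tail"),
    start = c(1, 24, 42, 55, 81, 90, 126, 131, 166, 206),
    end = c(23, 41, 54, 80, 89, 125, 130, 165, 205, 299))
  chain_topology(segments, ...)
}

#' Bead indices of the helical segments
#'
#' @param topology a `chain_topology`.
#' @return integer vector of bead indices belonging to segments labelled
#'   `H<number>`, the default atom selection for reaction coordinates and
#'   clustering (the flexible tail is excluded).
#' @export
helix_beads <- function(topology) {
  seg <- topology$segment_map
  hel <- seg[grepl("^H[0-9]+$", seg$label), , drop = FALSE]
  unlist(lapply(seq_len(nrow(hel)), function(k) hel$start[k]:hel$end[k]),
         use.names = FALSE)
}

# Indices of one named segment.
segment_beads <- function(topology, label) {
  seg <- topology$segment_map
  row <- seg[seg$label == label, , drop = FALSE]
  if (nrow(row) != 1L) stop("no segment labelled '", label, "'")
  row$start:row$end
}
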