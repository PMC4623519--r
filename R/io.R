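#' Write a coarse-grained model as a C-alpha PDB file
#'
#' One CA atom record per bead, 1-based residue numbering, the segment
#' label in the segid field.
#'
#' @param positions n x 3 coordinates, Angstrom.
#' @param topology the `chain_topology` supplying segment labels.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_pdb_ca <- function(positions, topology, file) {
  n <- topology$n_beads
  seg <- topology$segment_map
  segid <- character(n)
  for (k in seq_len(nrow(seg))) {
    segid[seg$start[k]:seg$end[k]] <- substr(seg$label[k], 1L, 4L)
  }
  bio3d::write.pdb(file = file, xyz = as.numeric(t(positions)),
                   type = rep("ATOM", n), resno = seq_len(n),
                   resid = rep("ALA", n), eleno = seq_len(n),
                   elety = rep("CA", n), chain = rep("A", n), segid = segid)
  invisible(file)
}

#' Read C-alpha coordinates from a PDB file
#'
#' @param file PDB path.
#' @return list with `positions` (n x 3 matrix of CA coordinates) and
#'   `resno` (residue numbers).
#' @export
read_pdb_ca <- function(file) {
  pdb <- bio3d::read.pdb(file)
  ca <- bio3d::atom.select(pdb, elety = "CA")
  xyz <- matrix(pdb$xyz[ca$xyz], ncol = 3L, byrow = TRUE)
  list(positions = xyz, resno = pdb$atom$resno[ca$atom])
}

#' Export a trajectory as plain-text XYZ
#'
#' One block per frame: bead count, a comment line with time / PE / KE,
#' then `CA x y z` rows. A lowest-common-denominator interchange format.
#'
#' @param traj a `dmd_trajectory`.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_xyz <- function(traj, file) {
  con <- file(file, "w")
  on.exit(close(con))
  n <- dim(traj$positions)[2L]
  for (f in seq_along(traj$times)) {
    writeLines(as.character(n), con)
    writeLines(sprintf("t= %.6f pe= %.9f ke= %.9f", traj$times[f],
                       traj$pe[f], traj$ke[f]), con)
    writeLines(sprintf("CA %.6f %.6f %.6f", traj$positions[f, , 1L],
                       traj$positions[f, , 2L], traj$positions[f, , 3L]), con)
  }
  invisible(file)
}

#' Export / import the pair-potential tables of a model
#'
#' JSON with one record per pair class member: bead indices, class, step
#' thresholds (Angstrom) and energy levels (kcal/mol; `"Inf"` encodes a
#' wall).
#'
#' @param model a `dmd_model`.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_potential_tables <- function(model, file) {
  tables <- lapply(model$pot_tables, function(tb) {
    list(thresholds = tb$thresholds,
         energies = ifelse(is.infinite(tb$energies), "Inf",
                           as.character(tb$energies)))
  })
  jsonlite::write_json(
    list(pairs = model$pairs, tables = tables),
    file, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' @rdname write_potential_tables
#' @export
read_potential_tables <- function(file) {
  raw <- jsonlite::read_json(file, simplifyVector = TRUE)
  tables <- lapply(seq_len(nrow(raw$tables)), function(k) {
    new_step_table(unlist(raw$tables$thresholds[k]),
                   as.numeric(unlist(raw$tables$energies[k])))
  })
  list(pairs = raw$pairs, tables = tables)
}

#' Write a heat-capacity curve as TSV
#'
#' Columns: reduced temperature, Kelvin, Cv (units of kB), uncertainty.
#'
#' @param cv a `cv_curve`.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_cv_tsv <- function(cv, file) {
  utils::write.table(cv$curve, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' Write a PMF surface as TSV
#'
#' First row: Rg bin edges; first column: RMSD bin edges; body: PMF in
#' kcal/mol with empty bins encoded as NA.
#'
#' @param surface a `free_energy_surface`.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_pmf_tsv <- function(surface, file) {
  m <- surface$pmf
  hdr <- paste(c("rmsd_edge\\rg_edge",
                 format(surface$rg_edges[-length(surface$rg_edges)])),
               collapse = "\t")
  rows <- vapply(seq_len(nrow(m)), function(r) {
    paste(c(format(surface$rmsd_edges[r]), format(m[r, ])), collapse = "\t")
  }, "")
  writeLines(c(hdr, rows), file)
  invisible(file)
}

#' Write cluster assignments as TSV
#'
#' Columns: frame, cluster, is_leader, is_centroid.
#'
#' @param clust a `cluster_result`.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_clusters_tsv <- function(clust, file) {
  nf <- length(clust$assignment)
  df <- data.frame(frame = seq_len(nf), cluster = clust$assignment,
                   is_leader = seq_len(nf) %in% clust$clusters$leader,
                   is_centroid = seq_len(nf) %in% clust$clusters$centroid)
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
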