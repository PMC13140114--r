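#' Write a trajectory as multi-model PDB
#'
#' Writes each frame as one MODEL/ENDMDL block of fixed-width ATOM (and,
#' for ligand atoms, HETATM) records: α-carbons named `CA` in chain A with
#' the given residue ids, ligand atoms as residue `LIG`. PDB coordinate
#' fields carry three decimals, so coordinates are stored at 0.001 Å
#' resolution.
#'
#' @param frames `F x N x 3` array of α-carbon coordinates.
#' @param path Output path.
#' @param residue_ids Integer residue numbers (default `1:N`).
#' @param ligand Optional `F x M x 3` array of ligand coordinates.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(frames, path, residue_ids = NULL,
                                 ligand = NULL) {
  assert_that(length(dim(frames)) == 3L && dim(frames)[3] == 3L,
              "frames must be an F x N x 3 array")
  nf <- dim(frames)[1]; n <- dim(frames)[2]
  residue_ids <- residue_ids %||% seq_len(n)
  assert_that(length(residue_ids) == n, "residue_ids length mismatch")
  if (!is.null(ligand)) {
    assert_that(dim(ligand)[1] == nf, "ligand frame count mismatch")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    serial <- 0L
    lines <- character(n)
    for (i in seq_len(n)) {
      serial <- serial + 1L
      lines[i] <- sprintf(
        "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, residue_ids[i], frames[f, i, 1], frames[f, i, 2], frames[f, i, 3])
    }
    writeLines(lines, con)
    if (!is.null(ligand)) {
      m <- dim(ligand)[2]
      llines <- character(m)
      for (i in seq_len(m)) {
        serial <- serial + 1L
        llines[i] <- sprintf(
          "HETATM%5d  C%-2d LIG A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, i %% 100, 9000L, ligand[f, i, 1], ligand[f, i, 2], ligand[f, i, 3])
      }
      writeLines(llines, con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model PDB trajectory
#'
#' Parses MODEL/ENDMDL blocks of fixed-width ATOM/HETATM records.
#' α-carbons are selected by atom name `CA` with blank or `A` altloc;
#' ligand atoms are selected by residue name.
#'
#' @param path PDB file path.
#' @param chain Chain identifier to keep (default `"A"`; `NULL` keeps all).
#' @param ligand_resname Residue name of the ligand (default `"LIG"`;
#'   `NULL` skips ligand extraction).
#' @return List with `frames` (`F x N x 3` array), `residue_ids`, and
#'   `ligand` (`F x M x 3` array or `NULL`).
#' @export
read_multimodel_pdb <- function(path, chain = "A", ligand_resname = "LIG") {
  assert_that(file.exists(path), paste("no such file:", path))
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  model_breaks <- cumsum(substr(lines, 1, 5) == "MODEL")
  if (max(model_breaks) == 0L) model_breaks <- rep(1L, length(lines))
  idx <- which(is_atom)
  assert_that(length(idx) > 0, paste0("no ATOM records in ", path))
  al <- lines[idx]
  atom_name <- trimws(substr(al, 13, 16))
  altloc <- substr(al, 17, 17)
  resname <- trimws(substr(al, 18, 20))
  ch <- substr(al, 22, 22)
  resid <- as.integer(substr(al, 23, 26))
  x <- as.numeric(substr(al, 31, 38))
  y <- as.numeric(substr(al, 39, 46))
  z <- as.numeric(substr(al, 47, 54))
  assert_that(!anyNA(x) && !anyNA(y) && !anyNA(z),
              paste0("malformed coordinate fields in ", path))
  model_of <- model_breaks[idx]
  keep_chain <- if (is.null(chain)) rep(TRUE, length(al)) else ch == chain
  ca <- atom_name == "CA" & (altloc == " " | altloc == "A") &
    rec[idx] == "ATOM  " & keep_chain
  models <- sort(unique(model_of))
  nf <- length(models)
  resids_first <- resid[ca & model_of == models[1]]
  n <- length(resids_first)
  assert_that(n > 0, paste0("no CA atoms found in ", path))
  frames <- array(NA_real_, c(nf, n, 3))
  for (k in seq_len(nf)) {
    sel <- ca & model_of == models[k]
    assert_that(sum(sel) == n,
                paste0("model ", k, " has a different CA count in ", path))
    frames[k, , 1] <- x[sel]; frames[k, , 2] <- y[sel]; frames[k, , 3] <- z[sel]
  }
  ligand <- NULL
  if (!is.null(ligand_resname)) {
    lig_sel <- resname == ligand_resname & keep_chain
    if (any(lig_sel)) {
      m <- sum(lig_sel & model_of == models[1])
      ligand <- array(NA_real_, c(nf, m, 3))
      for (k in seq_len(nf)) {
        sel <- lig_sel & model_of == models[k]
        assert_that(sum(sel) == m,
                    paste0("model ", k, " has a different ligand atom count in ", path))
        ligand[k, , 1] <- x[sel]; ligand[k, , 2] <- y[sel]; ligand[k, , 3] <- z[sel]
      }
    }
  }
  list(frames = frames, residue_ids = resids_first, ligand = ligand)
}
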