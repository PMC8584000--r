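# Optional bridge to a real docking engine (AutoDock-Vina-style).
# Ligand preparation uses the Open Babel command-line tool when present;
# engine output parsing and the best-pose rule work from text logs and
# are fully testable without any external binary.

#' Docking grid-box configuration
#'
#' Defaults reproduce a box centered on the ADP site of the WRN helicase
#' structure 6YHR: a 30 Angstrom cube with 31 grid elements per axis and
#' 9 independent docking runs per ligand.
#'
#' @param center_x,center_y,center_z box center (Angstrom).
#' @param edge box edge length (Angstrom).
#' @param grid_elements_per_axis grid points per axis.
#' @param n_poses independent docking runs / reported poses.
#' @return a `dg_docking_box` list.
#' @export
docking_box_config <- function(center_x = -21.277, center_y = -13.171,
                               center_z = 38.710, edge = 30,
                               grid_elements_per_axis = 31L, n_poses = 9L) {
  stopifnot(edge > 0, grid_elements_per_axis >= 2L, n_poses >= 1L)
  structure(
    list(center_x = center_x, center_y = center_y, center_z = center_z,
         edge = edge,
         grid_elements_per_axis = as.integer(grid_elements_per_axis),
         n_poses = as.integer(n_poses)),
    class = "dg_docking_box"
  )
}

#' Parse a docking engine result log
#'
#' Reads the tabular pose listing of an AutoDock-Vina-style log (columns
#' mode / affinity / rmsd) and returns the pose affinities in listed
#' order.
#'
#' @param text character vector of log lines (or a single string with
#'   newlines).
#' @return numeric vector of pose energies (kcal/mol).
#' @export
parse_engine_log <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  header <- grep("^\\s*mode\\s*\\|", lines)
  if (length(header) == 0L) {
    stop("no pose table header found in engine log")
  }
  body <- lines[(header[1L] + 1L):length(lines)]
  energies <- numeric(0)
  for (i in seq_along(body)) {
    ln <- body[i]
    # units continuation and separator lines of the header block
    if (grepl("^\\s*[|+-]", ln)) next
    m <- regmatches(ln, regexec(
      "^\\s*([0-9]+)\\s+(-?[0-9]+\\.?[0-9]*)\\s+", ln))[[1L]]
    if (length(m) == 3L) {
      energies <- c(energies, as.numeric(m[3L]))
    } else if (nzchar(trimws(ln))) {
      if (length(energies) > 0L) break
      stop("malformed pose table at line ", header[1L] + i, ": ", ln)
    }
  }
  energies
}

#' Best docking energy for one ligand
#'
#' Runs the docking engine (or accepts a pre-captured log) and returns
#' the minimum energy over the reported poses, the molecule's docking
#' score.
#'
#' @param ligand path to the prepared ligand file (PDBQT).
#' @param receptor path to the receptor file (PDBQT).
#' @param box a [docking_box_config()].
#' @param engine function `(ligand, receptor, box) -> log text`; defaults
#'   to invoking the `vina` binary, which must be installed. Supply a
#'   closure to use a different engine or a mock.
#' @param log pre-captured engine log text; when given, `engine` is not
#'   called.
#' @return best (minimum) pose energy in kcal/mol.
#' @export
dock_one <- function(ligand, receptor, box = docking_box_config(),
                     engine = NULL, log = NULL) {
  if (is.null(log)) {
    if (is.null(engine)) {
      vina <- Sys.which("vina")
      if (!nzchar(vina)) {
        stop("external dependency absent: no docking engine available ",
             "(install AutoDock Vina or pass `engine=`)")
      }
      engine <- function(ligand, receptor, box) {
        args <- c("--receptor", receptor, "--ligand", ligand,
                  "--center_x", box$center_x, "--center_y", box$center_y,
                  "--center_z", box$center_z,
                  "--size_x", box$edge, "--size_y", box$edge,
                  "--size_z", box$edge,
                  "--num_modes", box$n_poses)
        out <- system2(vina, args, stdout = TRUE, stderr = TRUE)
        paste(out, collapse = "\n")
      }
    }
    log <- engine(ligand, receptor, box)
  }
  poses <- parse_engine_log(log)
  if (length(poses) == 0L) stop("engine log contains no poses")
  min(poses)
}

#' Prepare a ligand file from SMILES
#'
#' Generates a 3D structure with hydrogens and Gasteiger partial charges
#' in PDBQT format using the `obabel` command-line tool.
#'
#' @param x SMILES or [molecule()] (single molecule).
#' @param workdir directory for the output file.
#' @param name output file stem.
#' @return path to the written PDBQT file.
#' @export
prepare_ligand <- function(x, workdir = tempdir(), name = "ligand") {
  canon <- as_canonical(x)
  stopifnot(length(canon) == 1L)
  obabel <- Sys.which("obabel")
  if (!nzchar(obabel)) {
    stop("external dependency absent: obabel binary not found on PATH")
  }
  out <- file.path(workdir, paste0(name, ".pdbqt"))
  status <- system2(obabel,
                    c(paste0("-:", shQuote(canon)), "-opdbqt", "-O",
                      shQuote(out), "--gen3d", "-h",
                      "--partialcharge", "gasteiger"),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(out)) {
    stop("ligand preparation failed for ", canon)
  }
  out
}
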