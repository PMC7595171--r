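#' Read a PDB file into a structure ensemble
#'
#' Reads single- or multi-MODEL PDB files via bio3d and returns a
#' [structure_ensemble()] (coordinates converted to nm). Residue numbering
#' is taken verbatim from the file. Alternate locations: only blank or 'A'
#' records are kept; insertion codes are rejected with an error because the
#' package's residue-range selections cannot represent them.
#'
#' @param path Path to a PDB file.
#' @param chain Optional chain identifier to keep (e.g. `"A"`).
#' @return A [structure_ensemble()].
#' @export
read_pdb_ensemble <- function(path, chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- at$type == "ATOM"
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  keep <- keep & (is.na(at$alt) | at$alt %in% c("", "A"))
  if (any(keep & !is.na(at$insert) & at$insert != "")) {
    stop("PDB file contains insertion codes; renumber the structure first",
         call. = FALSE)
  }
  idx <- which(keep)
  if (length(idx) == 0L) stop("no ATOM records selected", call. = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nf <- nrow(xyz)
  coords <- array(0, dim = c(nf, length(idx), 3L))
  cols <- as.vector(t(outer(idx - 1L, 1:3, function(a, b) 3L * a + b)))
  for (i in seq_len(nf)) {
    coords[i, , ] <- matrix(xyz[i, cols], ncol = 3L, byrow = TRUE) / 10
  }
  structure_ensemble(
    coords,
    data.frame(resno = at$resno[idx], resname = at$resid[idx],
               atom = at$elety[idx], stringsAsFactors = FALSE),
    provenance = paste0("pdb:", basename(path))
  )
}

#' Write a structure ensemble as a (multi-MODEL) PDB file
#'
#' Coordinates are written in Angstrom; one MODEL record per frame.
#'
#' @param ensemble A [structure_ensemble()].
#' @param path Output path.
#' @param chain Chain identifier to write.
#' @return `path`, invisibly.
#' @export
write_pdb_ensemble <- function(ensemble, path, chain = "A") {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  at <- ensemble$atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   generated by sh2states: %s",
                     ensemble$provenance), con)
  nf <- n_frames(ensemble)
  for (i in seq_len(nf)) {
    if (nf > 1L) writeLines(sprintf("MODEL     %4d", i), con)
    xyz <- nm_to_angstrom(frame_coords(ensemble, i))
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(nrow(at)),
      ifelse(nchar(at$atom) < 4, paste0(" ", at$atom), at$atom),
      at$resname, chain, at$resno, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0)
    writeLines(lines, con)
    if (nf > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Frame tables: the package's plain-text coordinate exchange format
#'
#' A frame table is a whitespace-separated text file with `#`-prefixed
#' header lines and columns `frame resno resname atom x y z`, coordinates
#' in nm.
#'
#' @param ensemble A [structure_ensemble()].
#' @param path Output path.
#' @return `path` (writer) or a [structure_ensemble()] (reader).
#' @export
write_frame_table <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sh2states frame table: %s", ensemble$provenance),
               "# columns: frame resno resname atom x y z (nm)"), con)
  nf <- n_frames(ensemble)
  at <- ensemble$atoms
  for (i in seq_len(nf)) {
    xyz <- frame_coords(ensemble, i)
    writeLines(sprintf("%d %d %s %s %.8g %.8g %.8g", i, at$resno,
                       at$resname, at$atom, xyz[, 1], xyz[, 2], xyz[, 3]),
               con)
  }
  invisible(path)
}

#' @rdname write_frame_table
#' @export
read_frame_table <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("frame", "resno", "resname", "atom",
                                        "x", "y", "z"),
                          stringsAsFactors = FALSE)
  frames <- sort(unique(df$frame))
  first <- df[df$frame == frames[1], ]
  atoms <- data.frame(resno = first$resno, resname = first$resname,
                      atom = first$atom, stringsAsFactors = FALSE)
  coords <- array(0, dim = c(length(frames), nrow(atoms), 3L))
  for (i in seq_along(frames)) {
    sub <- df[df$frame == frames[i], ]
    if (nrow(sub) != nrow(atoms)) {
      stop("frames disagree on atom count", call. = FALSE)
    }
    coords[i, , ] <- as.matrix(sub[, c("x", "y", "z")])
  }
  structure_ensemble(coords, atoms,
                     provenance = paste0("frame_table:", basename(path)))
}

#' Work-set tables
#'
#' Two-column plain-text tables (`direction work`), with `#` header lines
#' recording temperature, the stored true free-energy difference (if any)
#' and the sign convention: forward work is work done on the system for the
#' lambda 0 -> 1 transformation, reverse for 1 -> 0.
#'
#' @param work A [work_set()].
#' @param path Output path.
#' @return `path` (writer) or a [work_set()] (reader).
#' @export
write_work_table <- function(work, path) {
  stopifnot(inherits(work, "work_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# sh2states work table",
    "# sign convention: forward work = work done on the system for lambda 0->1; reverse for 1->0",
    sprintf("# temperature_K: %.6g", work$temperature),
    if (!is.null(work$true_dg)) sprintf("# true_dg_kJ_mol: %.10g", work$true_dg),
    "# columns: direction work_kJ_mol"), con)
  writeLines(c(sprintf("forward %.10g", work$forward_work),
               sprintf("reverse %.10g", work$reverse_work)), con)
  invisible(path)
}

#' @rdname write_work_table
#' @export
read_work_table <- function(path) {
  hdr <- grep("^#", readLines(path), value = TRUE)
  temp <- 300
  true_dg <- NULL
  for (h in hdr) {
    if (grepl("temperature_K:", h)) {
      temp <- as.numeric(sub(".*temperature_K:", "", h))
    }
    if (grepl("true_dg_kJ_mol:", h)) {
      true_dg <- as.numeric(sub(".*true_dg_kJ_mol:", "", h))
    }
  }
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("direction", "work"),
                          stringsAsFactors = FALSE)
  work_set(df$work[df$direction == "forward"],
           df$work[df$direction == "reverse"],
           temperature = temp, true_dg = true_dg)
}

#' Umbrella window sample tables
#'
#' Writes one two-column (`time value`) table per window, named
#' `<prefix>_window<i>.dat`, plus a YAML metadata file
#' `<prefix>_windows.yaml` with references, force constants and the
#' temperature — the layout common pull-code outputs use.
#'
#' @param windows An [umbrella_window_set()].
#' @param prefix Output path prefix.
#' @return The metadata path (writer) or an [umbrella_window_set()]
#'   (reader).
#' @export
write_window_tables <- function(windows, prefix) {
  stopifnot(inherits(windows, "umbrella_window_set"))
  n <- length(windows$references)
  files <- sprintf("%s_window%03d.dat", prefix, seq_len(n))
  for (i in seq_len(n)) {
    con <- file(files[i], "w")
    writeLines(c(sprintf("# umbrella window %d: ref %.6g nm, k %.6g kJ/mol/nm^2",
                         i, windows$references[i], windows$force_constants[i]),
                 "# columns: time_ps value_nm"), con)
    s <- windows$samples[[i]]
    writeLines(sprintf("%g %.10g", seq_along(s), s), con)
    close(con)
  }
  meta <- sprintf("%s_windows.yaml", prefix)
  yaml::write_yaml(list(
    temperature = windows$temperature,
    windows = lapply(seq_len(n), function(i) {
      list(file = basename(files[i]), reference = windows$references[i],
           force_constant = windows$force_constants[i])
    })), meta)
  invisible(meta)
}

#' @rdname write_window_tables
#' @param meta_path Path to the `_windows.yaml` metadata file.
#' @export
read_window_tables <- function(meta_path) {
  meta <- yaml::read_yaml(meta_path)
  dir <- dirname(meta_path)
  samples <- lapply(meta$windows, function(w) {
    utils::read.table(file.path(dir, w$file), header = FALSE,
                      comment.char = "#",
                      col.names = c("time", "value"))$value
  })
  umbrella_window_set(
    vapply(meta$windows, `[[`, numeric(1), "reference"),
    vapply(meta$windows, `[[`, numeric(1), "force_constant"),
    samples, temperature = meta$temperature)
}

#' Write a free-energy profile as a three-column table
#'
#' Columns `center G error` plus a JSON run record (tolerance, iterations,
#' window shifts F_i, offset convention) written beside it.
#'
#' @param profile A [wham_solve()] profile.
#' @param path Output path for the table; the run record goes to
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profile, path) {
  con <- file(path, "w")
  writeLines(c("# sh2states free-energy profile",
               sprintf("# offset convention: %s",
                       attr(profile, "offset_convention")),
               "# columns: center_nm G_kJ_mol error_kJ_mol"), con)
  writeLines(sprintf("%.8g %.8g %s", profile$center, profile$G,
                     ifelse(is.na(profile$error), "NA",
                            sprintf("%.8g", profile$error))), con)
  close(con)
  jsonlite::write_json(
    list(offset_convention = attr(profile, "offset_convention"),
         iterations = attr(profile, "iterations"),
         temperature = attr(profile, "temperature"),
         F_i = attr(profile, "F_i")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a collective vector as a JSON document
#'
#' Records the selection labels, mean structure, unit vector, eigenvalue
#' and variance fraction.
#'
#' @param cv A [collective_vector()].
#' @param path Output path.
#' @return `path` (writer) or a [collective_vector()] (reader).
#' @export
write_collective_vector <- function(cv, path) {
  stopifnot(inherits(cv, "collective_vector"))
  jsonlite::write_json(
    list(selection = cv$selection,
         mean_structure = cv$mean_structure,
         vector = cv$vector,
         eigenvalue = cv$eigenvalue,
         variance_fraction = cv$variance_fraction),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_collective_vector
#' @export
read_collective_vector <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  collective_vector(matrix(d$mean_structure, ncol = 3L), d$vector,
                    d$eigenvalue, d$variance_fraction,
                    as.data.frame(d$selection))
}
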