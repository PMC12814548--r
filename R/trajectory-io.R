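#' @title Trajectory input/output
#' @name trajectory-io
#' @description Readers for PDB topologies (via bio3d), multi-model PDB, DCD
#'   and a whitespace XYZ dialect with an explicit box/unit comment line;
#'   writers for the same XYZ dialect and PDB. All coordinates are converted
#'   to nm on input (PDB and DCD are Angstrom by convention; the XYZ header
#'   names its unit).
NULL

rlError <- function(msg, class) {
  stop(structure(class = c(class, "ringlink_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

ION_MASSES <- c(NA_ = 22.990, CA = 40.078, MG = 24.305, CL = 35.453,
                K = 39.098)
BEAD_MASS <- 94.97  # one phosphate group per bead

speciesFromResidue <- function(resid) {
  r <- toupper(trimws(resid))
  ifelse(r %in% c("NA", "NA+", "SOD"), "NA",
  ifelse(r %in% c("CA", "CA2", "CAL"), "CA",
  ifelse(r %in% c("MG", "MG2"), "MG",
  ifelse(r %in% c("CL", "CL-", "CLA"), "CL", "DNA"))))
}

massFromSpecies <- function(species) {
  m <- c("NA" = 22.990, CA = 40.078, MG = 24.305, CL = 35.453)
  out <- unname(m[species])
  out[is.na(out)] <- BEAD_MASS
  out
}

#' Read a PDB topology and assign ring membership
#'
#' Ring membership is taken from an explicit chain-to-ring map rather than
#' inferred from connectivity; chains absent from the map get `ring_id = -1`
#' (ions, solvent). Species are recognized from residue names
#' (NA/CA/MG/CL and common force-field aliases); everything else is labelled
#' `DNA`.
#'
#' @param path path to a PDB file.
#' @param ringMap named integer vector mapping chain IDs to ring ids 0/1,
#'   e.g. `c(A = 0, B = 1)`.
#' @return data.frame of atom metadata (see [Trajectory-class]).
#' @export
readTopology <- function(path, ringMap = c(A = 0, B = 1)) {
  if (!file.exists(path) || file.size(path) == 0)
    rlError(paste("unreadable or empty topology file:", path),
            "ringlink_format_error")
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e)
                    rlError(paste("not a parseable PDB:", conditionMessage(e)),
                            "ringlink_format_error"))
  a <- pdb$atom
  chains <- unique(a$chain)
  missing_chains <- setdiff(names(ringMap), chains)
  if (length(missing_chains))
    rlError(paste("ring map names chains absent from topology:",
                  paste(missing_chains, collapse = ", ")),
            "ringlink_config_error")
  ring_id <- rep(-1L, nrow(a))
  for (ch in names(ringMap))
    ring_id[a$chain == ch] <- as.integer(ringMap[[ch]])
  species <- speciesFromResidue(a$resid)
  species[ring_id >= 0L] <- "DNA"
  data.frame(atom_index = seq_len(nrow(a)) - 1L,
             atom_name = trimws(a$elety),
             residue_index = as.integer(a$resno),
             residue_name = trimws(a$resid),
             chain_id = as.character(a$chain),
             ring_id = ring_id,
             species = species,
             mass = massFromSpecies(species),
             stringsAsFactors = FALSE)
}

#' Resolve a declarative atom selection
#'
#' Predicates combine with AND; `NULL` predicates are ignored. The result is
#' a deterministic sorted vector of unique 1-based row indices into the atom
#' table (the table's own `atom_index` column stays 0-based). An empty
#' selection is legal.
#'
#' @param atoms atom metadata data.frame.
#' @param atomName character vector of atom names to keep (set membership).
#' @param species single species string (e.g. `"MG"`).
#' @param ringId single ring id (0, 1, or -1).
#' @param residueIndex integer vector of residue indices to keep.
#' @return sorted integer vector of 1-based atom row indices.
#' @export
resolveSelection <- function(atoms, atomName = NULL, species = NULL,
                             ringId = NULL, residueIndex = NULL) {
  keep <- rep(TRUE, nrow(atoms))
  if (!is.null(atomName)) keep <- keep & atoms$atom_name %in% atomName
  if (!is.null(species)) keep <- keep & atoms$species == species
  if (!is.null(ringId)) keep <- keep & atoms$ring_id == as.integer(ringId)
  if (!is.null(residueIndex)) keep <- keep & atoms$residue_index %in% residueIndex
  sort(unique(which(keep)))
}

parseXYZHeader <- function(line) {
  toks <- strsplit(trimws(line), "\\s+")[[1]]
  kv <- list()
  vals <- character(0)
  for (t in toks) {
    if (grepl("=", t, fixed = TRUE)) {
      p <- strsplit(t, "=", fixed = TRUE)[[1]]
      kv[[p[1]]] <- p[2]
      last <- p[1]
    } else if (exists("last", inherits = FALSE) && last == "box" &&
               !is.na(suppressWarnings(as.numeric(t)))) {
      vals <- c(vals, t)
    }
  }
  box <- suppressWarnings(as.numeric(c(kv[["box"]], vals)))
  if (length(box) != 3L || any(is.na(box)))
    rlError("XYZ header must carry 'box=X Y Z'", "ringlink_format_error")
  unit <- kv[["unit"]]
  if (is.null(unit))
    rlError("XYZ header must carry 'unit=nm' or 'unit=angstrom'",
            "ringlink_format_error")
  list(box = box, unit = unit,
       frame = suppressWarnings(as.integer(kv[["frame"]])),
       time = suppressWarnings(as.numeric(kv[["time"]])))
}

unitScale <- function(unit) {
  switch(tolower(unit),
         nm = 1, angstrom = 0.1, a = 0.1, ang = 0.1,
         rlError(paste("unknown length unit:", unit), "ringlink_format_error"))
}

readFramesXYZ <- function(path, natoms_expected, stride) {
  lines <- readLines(path)
  nline <- length(lines)
  out_coords <- list()
  out_box <- list()
  out_time <- numeric(0)
  out_fidx <- integer(0)
  pos <- 1L
  fi <- 0L
  kept <- 0L
  while (pos <= nline) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat))
      rlError("malformed XYZ frame header (atom count)", "ringlink_format_error")
    if (nat != natoms_expected)
      rlError(sprintf("XYZ frame has %d atoms, topology has %d",
                      nat, natoms_expected), "ringlink_consistency_error")
    hdr <- parseXYZHeader(lines[pos + 1L])
    sc <- unitScale(hdr$unit)
    body <- lines[(pos + 2L):(pos + 1L + nat)]
    if (fi %% stride == 0L) {
      con <- textConnection(body)
      m <- scan(con, what = list(character(), double(), double(), double()),
                quiet = TRUE)
      close(con)
      kept <- kept + 1L
      out_coords[[kept]] <- cbind(m[[2]], m[[3]], m[[4]]) * sc
      out_box[[kept]] <- hdr$box * sc
      out_time <- c(out_time, if (is.na(hdr$time)) fi else hdr$time)
      out_fidx <- c(out_fidx, if (is.na(hdr$frame)) fi else hdr$frame)
    }
    pos <- pos + 2L + nat
    fi <- fi + 1L
  }
  if (!kept) rlError("no frames found in XYZ file", "ringlink_format_error")
  list(coords = out_coords, box = out_box, time = out_time, fidx = out_fidx)
}

readFramesPDB <- function(path, natoms_expected, stride) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    rlError(paste("not a parseable PDB:", conditionMessage(e)),
                            "ringlink_format_error"))
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  nat <- ncol(xyz) / 3
  if (nat != natoms_expected)
    rlError(sprintf("PDB frames have %d atoms, topology has %d",
                    nat, natoms_expected), "ringlink_consistency_error")
  box <- c(100, 100, 100)  # Angstrom fallback when CRYST1 is absent
  cr <- pdb$cryst1
  if (!is.null(cr) && length(cr$abc) == 3 && all(is.finite(cr$abc)) &&
      all(cr$abc > 0)) {
    if (!is.null(cr$angles) && any(abs(cr$angles - 90) > 1e-3))
      rlError("triclinic boxes are not supported", "ringlink_format_error")
    box <- cr$abc
  }
  keep <- seq(1, nrow(xyz), by = stride)
  coords <- lapply(keep, function(i)
    matrix(xyz[i, ], ncol = 3, byrow = TRUE) * 0.1)
  list(coords = coords, box = rep(list(box * 0.1), length(keep)),
       time = as.numeric(keep - 1L), fidx = as.integer(keep - 1L))
}

readFramesDCD <- function(path, natoms_expected, stride) {
  dcd <- tryCatch(bio3d::read.dcd(path, cell = FALSE, verbose = FALSE),
                  error = function(e)
                    rlError(paste("not a parseable DCD:", conditionMessage(e)),
                            "ringlink_format_error"))
  cell <- tryCatch(bio3d::read.dcd(path, cell = TRUE, verbose = FALSE),
                   error = function(e) NULL)
  if (!is.matrix(dcd)) dcd <- matrix(dcd, nrow = 1)
  nat <- ncol(dcd) / 3
  if (nat != natoms_expected)
    rlError(sprintf("DCD frames have %d atoms, topology has %d",
                    nat, natoms_expected), "ringlink_consistency_error")
  keep <- seq(1, nrow(dcd), by = stride)
  coords <- lapply(keep, function(i)
    matrix(dcd[i, ], ncol = 3, byrow = TRUE) * 0.1)
  boxes <- lapply(keep, function(i) {
    if (is.matrix(cell) && ncol(cell) >= 6) {
      ang <- cell[i, 4:6]
      if (any(abs(ang - 90) > 1e-3))
        rlError("triclinic boxes are not supported", "ringlink_format_error")
      cell[i, 1:3] * 0.1
    } else c(10, 10, 10)
  })
  list(coords = coords, box = boxes, time = as.numeric(keep - 1L),
       fidx = as.integer(keep - 1L))
}

#' Read coordinate frames into a Trajectory
#'
#' @param path coordinate file (XYZ dialect with `box=`/`unit=` header,
#'   multi-model PDB, or DCD).
#' @param atoms atom metadata from [readTopology()] (or the generator).
#' @param stride keep every stride-th frame (>= 1).
#' @param format `"auto"` (by extension), `"xyz"`, `"pdb"` or `"dcd"`.
#' @return a [Trajectory-class] object with coordinates in nm.
#' @export
readFrames <- function(path, atoms, stride = 1L,
                       format = c("auto", "xyz", "pdb", "dcd")) {
  format <- match.arg(format)
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L)
    rlError("stride must be >= 1", "ringlink_usage_error")
  if (!file.exists(path))
    rlError(paste("missing trajectory file:", path), "ringlink_format_error")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xyz = "xyz", pdb = "pdb", dcd = "dcd",
                     rlError(paste("cannot infer trajectory format from:", path),
                             "ringlink_format_error"))
  }
  res <- switch(format,
                xyz = readFramesXYZ(path, nrow(atoms), stride),
                pdb = readFramesPDB(path, nrow(atoms), stride),
                dcd = readFramesDCD(path, nrow(atoms), stride))
  nf <- length(res$coords)
  coords <- array(0, dim = c(nrow(atoms), 3, nf))
  for (i in seq_len(nf)) coords[, , i] <- res$coords[[i]]
  box <- vapply(res$box, identity, numeric(3))
  new("Trajectory", atoms = atoms, coords = coords,
      box = matrix(box, nrow = 3), time = res$time, frameIndex = res$fidx)
}

#' Write a Trajectory in the package's XYZ dialect
#'
#' One block per frame: an atom-count line, a header line
#' `frame=<i> time=<t> box=<x> <y> <z> unit=nm`, then `name x y z` rows
#' (nm, 6 decimals).
#'
#' @param traj a [Trajectory-class] object.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeFramesXYZ <- function(traj, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  nm <- traj@atoms$atom_name
  for (i in seq_len(nFrames(traj))) {
    b <- traj@box[, i]
    writeLines(c(as.character(nAtoms(traj)),
                 sprintf("frame=%d time=%.4f box=%.6f %.6f %.6f unit=nm",
                         traj@frameIndex[i], traj@time[i], b[1], b[2], b[3])),
               con)
    m <- traj@coords[, , i]
    writeLines(sprintf("%-6s %12.6f %12.6f %12.6f", nm, m[, 1], m[, 2], m[, 3]),
               con)
  }
  invisible(path)
}

#' Write a topology (plus one frame) as PDB
#'
#' Coordinates are converted from nm to Angstrom; the box is recorded on a
#' CRYST1 record with 90-degree angles.
#'
#' @param atoms atom metadata data.frame.
#' @param coords `nAtoms x 3` matrix, nm.
#' @param box numeric vector of 3 edges, nm.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeTopologyPDB <- function(atoms, coords, box, path) {
  xyz <- as.numeric(t(coords * 10))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("ATOM", nrow(atoms)),
                   resno = atoms$residue_index,
                   resid = atoms$residue_name,
                   eleno = seq_len(nrow(atoms)),
                   elety = atoms$atom_name,
                   chain = atoms$chain_id)
  lines <- readLines(path)
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   box[1] * 10, box[2] * 10, box[3] * 10, 90, 90, 90)
  writeLines(c(cryst, lines), path)
  invisible(path)
}
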