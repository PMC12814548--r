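#' @title Pipeline orchestration
#' @name pipeline
#' @description A single entry point running generate -> analyze
#'   (shape | potential | orientation | ions | rigidmodel) from a shared
#'   YAML configuration, writing TSV/JSON outputs plus a run manifest with
#'   config hash, seeds and input checksums. A thin command-line wrapper
#'   lives at `inst/scripts/ringlink-cli.R`.
NULL

configGet <- function(cfg, path, default = NULL, required = FALSE) {
  node <- cfg
  for (p in strsplit(path, ".", fixed = TRUE)[[1]]) {
    if (is.null(node[[p]])) {
      if (required)
        rlError(paste0("config field missing: ", path), "ringlink_usage_error")
      return(default)
    }
    node <- node[[p]]
  }
  node
}

writeTSV <- function(df, path, comment = NULL) {
  con <- file(path, "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

runManifest <- function(configPath, cfg, outDir, seed, inputs) {
  checks <- list()
  for (f in inputs)
    if (!is.null(f) && file.exists(f))
      checks[[basename(f)]] <- unname(tools::md5sum(f))
  list(config = basename(configPath),
       config_md5 = unname(tools::md5sum(configPath)),
       seed = seed,
       package = "ringlink",
       version = as.character(utils::packageVersion("ringlink")),
       input_md5 = checks,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

loadTrajectoryFromConfig <- function(cfg, stride) {
  topo <- configGet(cfg, "topology", required = TRUE)
  trj <- configGet(cfg, "trajectory", required = TRUE)
  if (!file.exists(topo))
    rlError(paste("config field 'topology' names a missing file:", topo),
            "ringlink_usage_error")
  if (!file.exists(trj))
    rlError(paste("config field 'trajectory' names a missing file:", trj),
            "ringlink_usage_error")
  rm <- configGet(cfg, "ring_map", default = list(A = 0, B = 1))
  ringMap <- setNames(as.integer(unlist(rm)), names(rm))
  atoms <- readTopology(topo, ringMap)
  readFrames(trj, atoms, stride = stride)
}

specFromConfig <- function(g) {
  args <- list()
  take <- function(cfgName, argName, cast = identity) {
    v <- g[[cfgName]]
    if (!is.null(v)) args[[argName]] <<- cast(v)
  }
  take("n_beads", "nBeads", as.integer)
  take("ring_radius", "ringRadius", as.numeric)
  take("eccentricity", "eccentricity", as.numeric)
  take("bend_amplitude", "bendAmplitude", as.numeric)
  take("box_edge", "boxEdge", as.numeric)
  take("n_frames", "nFrames", as.integer)
  take("seed", "seed", as.integer)
  if (!is.null(g$separation_model))
    args$separationModel <- as.data.frame(do.call(rbind,
      lapply(g$separation_model, as.data.frame)))
  if (!is.null(g$orientation_model))
    args$orientationModel <- unlist(g$orientation_model)
  if (!is.null(g$ions))
    args$ions <- as.data.frame(do.call(rbind, lapply(g$ions, as.data.frame)))
  if (!is.null(g$bridge_script))
    args$bridgeScript <- as.data.frame(do.call(rbind,
      lapply(g$bridge_script, as.data.frame)))
  do.call(syntheticSpec, args)
}

#' Run one pipeline stage from a configuration file
#'
#' Subcommands: `generate` (write a synthetic trajectory), `shape`
#' (per-ring shape summaries), `potential` (separation series, g(r),
#' effective potential, minima/plateaus, per-state shape tables),
#' `orientation` (per-frame angles, density grid, mode), `ions` (per-group
#' RDFs, condensed fractions, contacts, bridges), `rigidmodel` (analytic
#' insertion density and linked-circle Monte Carlo). Every run writes a
#' `manifest.json` with the config hash, seed, package version and input
#' checksums; identical config + inputs reproduce identical tables.
#'
#' @param subcommand one of `"generate"`, `"shape"`, `"potential"`,
#'   `"orientation"`, `"ions"`, `"rigidmodel"`.
#' @param configPath path to a YAML configuration file.
#' @param outDir output directory (created if absent).
#' @param seed optional integer overriding the config seed.
#' @param stride optional stride overriding the config stride.
#' @return invisibly, a named list of written file paths.
#' @export
runAnalysis <- function(subcommand, configPath, outDir, seed = NULL,
                        stride = NULL) {
  subcommand <- match.arg(subcommand,
                          c("generate", "shape", "potential", "orientation",
                            "ions", "rigidmodel"))
  if (!file.exists(configPath))
    rlError(paste("config file not found:", configPath),
            "ringlink_usage_error")
  cfg <- yaml::read_yaml(configPath)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (!is.null(seed)) as.integer(seed)
  else as.integer(configGet(cfg, "seed", default = 1L))
  stride <- if (!is.null(stride)) as.integer(stride)
  else as.integer(configGet(cfg, "stride", default = 1L))
  outputs <- list()
  emit <- function(name, path) outputs[[name]] <<- path

  if (subcommand == "generate") {
    g <- configGet(cfg, "generate", required = TRUE)
    g$seed <- seed
    spec <- specFromConfig(g)
    generateCatenane(spec, dir = outDir)
    emit("topology", file.path(outDir, "topology.pdb"))
    emit("trajectory", file.path(outDir, "traj.xyz"))
    emit("ground_truth", file.path(outDir, "ground_truth.json"))
  } else if (subcommand == "rigidmodel") {
    R <- as.numeric(configGet(cfg, "rigidmodel.radius", default = 1))
    ns <- as.numeric(configGet(cfg, "rigidmodel.n_samples", default = 1e5))
    mc <- mcLinkedCircles(R = R, nSamples = ns, seed = seed)
    rg <- seq(0, 2 * R, length.out = 201)
    writeTSV(data.frame(r = rg, p = insertionProbability(rg, R),
                        p_normalized = insertionProbability(rg, R, TRUE)),
             file.path(outDir, "insertion_density.tsv"),
             "analytic rigid-ring insertion density")
    writeTSV(mc$histogram, file.path(outDir, "histogram.tsv"),
             "linked-circle COM-distance histogram")
    writeTSV(data.frame(r = mc$samples), file.path(outDir, "samples.tsv"),
             "accepted COM distances")
    jsonlite::write_json(list(mode = mc$mode,
                              mode_over_R = mc$mode / R,
                              analytic_insertion_mode = insertionMode(R),
                              acceptance_rate = mc$acceptanceRate,
                              n_samples = length(mc$samples),
                              seed = seed),
                         file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    emit("summary", file.path(outDir, "summary.json"))
  } else {
    traj <- loadTrajectoryFromConfig(cfg, stride)
    atoms <- atomData(traj)
    ringA <- resolveSelection(atoms, ringId = 0)
    ringB <- resolveSelection(atoms, ringId = 1)
    if (subcommand == "shape") {
      nb <- as.integer(configGet(cfg, "shape.n_blocks", default = 5L))
      tab <- rbind(cbind(ring = 0L, shapeSummary(ringSpectra(traj, ringA), nb)),
                   cbind(ring = 1L, shapeSummary(ringSpectra(traj, ringB), nb)))
      writeTSV(tab, file.path(outDir, "shape_summary.tsv"),
               "per-ring gyration shape descriptors (nm, nm^2)")
      emit("shape_summary", file.path(outDir, "shape_summary.tsv"))
    } else if (subcommand == "potential") {
      bw <- as.numeric(configGet(cfg, "potential.bin_width", default = 0.05))
      sw <- as.integer(configGet(cfg, "potential.smooth_window", default = 5L))
      bm <- as.numeric(configGet(cfg, "potential.barrier_min", default = 0.2))
      pt <- as.numeric(configGet(cfg, "potential.plateau_tol", default = 0.15))
      ps <- as.integer(configGet(cfg, "potential.plateau_span", default = 6L))
      ser <- separationSeries(traj, ringA, ringB)
      rd <- comPairDistribution(ser, binWidth = bw)
      ep <- findMinima(effectivePotential(rd), sw, bm, pt, ps)
      writeTSV(ser, file.path(outDir, "separation.tsv"), "COM separation (nm)")
      writeTSV(data.frame(r = binCenters(rd), g = rd@g, counts = rd@counts,
                          beta_V = ep@betaV),
               file.path(outDir, "effective_potential.tsv"),
               "g(r) (pair_density) and betaV = -ln g, min-shifted (kBT)")
      jsonlite::write_json(list(minima = potentialMinima(ep),
                                plateaus = potentialPlateaus(ep)),
                           file.path(outDir, "minima.json"), digits = NA)
      if (nrow(potentialMinima(ep))) {
        st <- assignStates(ser, ep)
        specA <- ringSpectra(traj, ringA)
        rows <- lapply(sort(unique(st)), function(s) {
          idx <- which(st == s)
          if (length(idx) < 2) return(NULL)
          cbind(state = s, n_frames = length(idx),
                shapeSummary(list(eigenvalues =
                  specA$eigenvalues[idx, , drop = FALSE]),
                  nBlocks = min(5L, length(idx))))
        })
        rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
        if (!is.null(rows))
          writeTSV(rows, file.path(outDir, "state_shape.tsv"),
                   "ring-0 shape descriptors per separation basin")
      }
      emit("effective_potential", file.path(outDir, "effective_potential.tsv"))
    } else if (subcommand == "orientation") {
      sg <- as.numeric(configGet(cfg, "orientation.sigma", default = 0.3))
      gs <- as.integer(configGet(cfg, "orientation.grid", default = 100L))
      ch <- configGet(cfg, "orientation.eigenvector", default = "smallest")
      os <- orientationSeries(traj, ringA, ringB, choice = ch)
      map <- kde2D(os, sigma = sg, gridSize = c(gs, gs))
      writeTSV(os, file.path(outDir, "orientation.tsv"),
               "per-frame COM separation (nm) and plane angle (degrees)")
      dens <- data.frame(r = rep(map@rGrid, times = length(map@thetaGrid)),
                         theta = rep(map@thetaGrid, each = length(map@rGrid)),
                         density = as.vector(map@density))
      writeTSV(dens, file.path(outDir, "density_grid.tsv"),
               "2D KDE of (r, theta), normalized on the grid")
      m <- densityMode(map)
      jsonlite::write_json(list(mode_r = m[["r"]], mode_theta = m[["theta"]],
                                sigma = sg, eigenvector = ch),
                           file.path(outDir, "density_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      emit("density_summary", file.path(outDir, "density_summary.json"))
    } else if (subcommand == "ions") {
      rmax <- as.numeric(configGet(cfg, "ions.r_max", default = 1.2))
      bw <- as.numeric(configGet(cfg, "ions.bin_width", default = 0.002))
      cut <- as.numeric(configGet(cfg, "ions.cutoff", default = 0.6))
      groups <- configGet(cfg, "ions.groups",
                          default = list(OP = c("O1P", "O2P"), O2 = "O2",
                                         major = c("O4", "O6")))
      speciesList <- configGet(cfg, "ions.species",
                               default = setdiff(unique(
                                 atoms$species[atoms$ring_id == -1L]), "CL"))
      dna <- resolveSelection(atoms, ringId = 0)
      dna <- sort(c(dna, resolveSelection(atoms, ringId = 1)))
      condensed <- list()
      for (sp in speciesList) {
        ions <- resolveSelection(atoms, species = sp)
        if (!length(ions)) next
        for (gname in names(groups)) {
          tg <- resolveSelection(atoms, atomName = unlist(groups[[gname]]))
          if (!length(tg)) next
          rd <- ionRDF(traj, ions, tg, rMax = rmax, binWidth = bw)
          fp <- firstPeak(rd)
          writeTSV(data.frame(r = binCenters(rd), g = rd@g,
                              counts = rd@counts),
                   file.path(outDir, sprintf("rdf_%s_%s.tsv", sp, gname)),
                   sprintf("ion RDF %s vs %s%s", sp, gname,
                           if (nrow(fp)) sprintf("; first peak %.3f nm", fp$r_peak)
                           else ""))
        }
        condensed[[sp]] <- condensedFraction(traj, ions, dna, cut)$mean
      }
      ct <- contactResidues(traj, ringA, ringB, cut)
      writeTSV(ct$persistence, file.path(outDir, "contacts.tsv"),
               sprintf("inter-ring residue contacts, cutoff %.2f nm", cut))
      allCations <- resolveSelection(atoms, ringId = -1)
      allCations <- allCations[atoms$species[allCations] != "CL"]
      br <- ionBridges(traj, allCations, ringA, ringB, cut)
      ev <- br$events
      ev$partners_A <- NULL
      ev$partners_B <- NULL
      writeTSV(ev, file.path(outDir, "bridges.tsv"),
               "ion bridge events (1-based atom row, 0-based frames)")
      jsonlite::write_json(list(condensed_fraction = condensed,
                                cutoff = cut),
                           file.path(outDir, "condensed.json"),
                           auto_unbox = TRUE, digits = NA)
      emit("condensed", file.path(outDir, "condensed.json"))
    }
  }
  manifest <- runManifest(configPath, cfg, outDir, seed,
                          c(configGet(cfg, "topology"),
                            configGet(cfg, "trajectory")))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  emit("manifest", file.path(outDir, "manifest.json"))
  invisible(outputs)
}
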