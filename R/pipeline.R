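# Run configuration, the scan/report drivers and their file outputs. All
# thresholds (contact cutoffs, cluster cutoff, hydrogen-bond geometry) are
# surfaced here with their standard defaults.

.CONFIG_KEYS <- list(
  scan = c("topology", "trajectories", "criterion", "probe_residues",
           "contact_cutoff", "bond_com_mode", "frame_stride",
           "refractory_time", "frame_interval", "seed", "out_dir"),
  geometry = c("structure", "sasa_mode", "sasa_points", "probe_radius"),
  conformation = c("topology", "trajectory", "reference", "discard_ps",
                   "cluster_cutoff", "sasa_points", "hbond", "domains",
                   "frame_interval"),
  msquant = c("peak_table", "sample", "residue_offset"))

#' Read and validate a YAML run configuration
#'
#' Recognised sections: \code{scan}, \code{geometry}, \code{conformation},
#' \code{msquant}; unknown sections or keys are rejected so typos fail
#' before any computation.
#'
#' @param path YAML file.
#' @return validated nested list with class \code{"RunConfig"}.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  badSection <- setdiff(names(cfg), names(.CONFIG_KEYS))
  if (length(badSection)) {
    stop("unknown config section(s): ", paste(badSection, collapse = ", "))
  }
  for (sec in names(cfg)) {
    badKey <- setdiff(names(cfg[[sec]]), .CONFIG_KEYS[[sec]])
    if (length(badKey)) {
      stop("unknown key(s) in section ", sec, ": ",
           paste(badKey, collapse = ", "))
    }
  }
  structure(cfg, class = "RunConfig")
}

.scanDefaults <- function(cfg) {
  utils::modifyList(list(criterion = "distance",
                         probe_residues = c(.TCEP_NAMES, .DTT_NAMES),
                         contact_cutoff = NULL, bond_com_mode = "SG_only",
                         frame_stride = 1, refractory_time = 100,
                         frame_interval = 1, seed = 1, out_dir = "."),
                    cfg)
}

#' Apply a reduction criterion to a set of trajectories and aggregate
#'
#' Loads the topology and each trajectory, applies the configured
#' criterion, aggregates the per-trajectory calls into a lability report
#' and writes \code{report.json}, \code{calls.csv} and
#' \code{distance_stats.csv} (the per-bond five-number summaries of the
#' proximity statistics) to the output directory. On any stage error the
#' partial outputs are removed and the error propagates.
#'
#' @param scanConfig list: \code{topology} (path), \code{trajectories}
#'   (paths), \code{criterion} ("distance" or "distance_energy"),
#'   \code{probe_residues}, \code{contact_cutoff} (default by probe kind),
#'   \code{bond_com_mode}, \code{frame_stride}, \code{refractory_time},
#'   \code{frame_interval} (ps between frames when the format has no
#'   times), \code{out_dir}.
#' @param energyBackend optional energy backend passed through to the
#'   distance+energy criterion.
#' @return the \code{LabilityReport}, invisibly.
#' @export
runScan <- function(scanConfig, energyBackend = NULL) {
  sc <- .scanDefaults(scanConfig)
  if (is.null(sc$topology)) stop("scan config needs a topology path")
  if (is.null(sc$trajectories) || length(sc$trajectories) < 1) {
    stop("scan config needs at least one trajectory")
  }
  if (!sc$criterion %in% c("distance", "distance_energy")) {
    stop("criterion must be 'distance' or 'distance_energy'")
  }
  dir.create(sc$out_dir, showWarnings = FALSE, recursive = TRUE)
  outFiles <- file.path(sc$out_dir,
                        c("report.json", "calls.csv", "distance_stats.csv"))
  ok <- FALSE
  on.exit(if (!ok) unlink(outFiles), add = TRUE)

  topo <- readStructure(sc$topology)
  bonds <- detectDisulfides(topo)
  if (nrow(bonds) == 0) stop("no disulfide bonds found in the topology")
  probes <- selectProbes(topo, residueNames = sc$probe_residues)
  if (length(probes@molecules) == 0) {
    stop("no probe molecules found (residue names ",
         paste(sc$probe_residues, collapse = ", "), ")")
  }
  cutoff <- if (is.null(sc$contact_cutoff)) {
    defaultContactCutoff(probes@kind)
  } else {
    sc$contact_cutoff
  }
  pcfg <- proximityConfig(contactCutoff = cutoff,
                          bondComMode = sc$bond_com_mode,
                          frameStride = sc$frame_stride)
  calls <- vector("list", length(sc$trajectories))
  statsAll <- NULL
  for (i in seq_along(sc$trajectories)) {
    traj <- readTrajectory(sc$trajectories[i], topo,
                           frameInterval = sc$frame_interval)
    id <- basename(sc$trajectories[i])
    calls[[i]] <- if (sc$criterion == "distance") {
      scanDistanceCriterion(traj, bonds, probes, pcfg, trajectoryId = id)
    } else {
      scanDistanceEnergyCriterion(traj, bonds, probes, pcfg,
                                  refractoryTime = sc$refractory_time,
                                  backend = energyBackend,
                                  trajectoryId = id)
    }
    st <- distanceStats(traj, bonds, probes, pcfg)$summary
    st$trajectory <- id
    statsAll <- rbind(statsAll, st)
  }
  report <- aggregateLability(calls, bondLabels = bonds$label)

  callDf <- do.call(rbind, lapply(calls, function(cl) {
    data.frame(trajectory = cl$trajectoryId, criterion = cl$criterion,
               called_bond = ifelse(is.na(cl$calledBond), "",
                                    cl$calledBond),
               frame = if (is.null(cl$event)) NA else cl$event$frameIndex,
               time_ps = if (is.null(cl$event)) NA else cl$event$time,
               distance_nm = if (is.null(cl$event)) NA else
                 cl$event$distance,
               energy_checks_failed = cl$energyChecksFailed,
               stringsAsFactors = FALSE)
  }))
  js <- list(criterion = report@criterion,
             n_trajectories = report@nTrajectories,
             probabilities = as.list(report@probabilities),
             no_call_fraction = report@noCallFraction,
             contact_cutoff_nm = cutoff, probe_kind = probes@kind)
  writeLines(as.character(jsonlite::toJSON(js, auto_unbox = TRUE,
                                           digits = NA, pretty = TRUE)),
             outFiles[1])
  utils::write.csv(callDf, outFiles[2], row.names = FALSE)
  utils::write.csv(statsAll, outFiles[3], row.names = FALSE)
  ok <- TRUE
  invisible(report)
}

#' Assemble a combined geometry / conformation / MS report
#'
#' Runs whichever sections are present in the configuration and writes one
#' JSON file with stable key order (so repeated runs on identical inputs
#' are byte-identical).
#'
#' @param cfg a \code{RunConfig} (or plain list) with any of the sections
#'   \code{geometry}, \code{conformation}, \code{msquant}.
#' @param outFile output JSON path.
#' @return the report list, invisibly.
#' @export
runReport <- function(cfg, outFile = "report.json") {
  ok <- FALSE
  on.exit(if (!ok) unlink(outFile), add = TRUE)
  out <- list()
  if (!is.null(cfg$geometry)) {
    g <- cfg$geometry
    s <- readStructure(g$structure)
    out$geometry <- geometryTable(
      s, sasaMode = if (is.null(g$sasa_mode)) "SG_only" else g$sasa_mode,
      nPoints = if (is.null(g$sasa_points)) 960L else g$sasa_points,
      probeRadius = if (is.null(g$probe_radius)) 1.4 else g$probe_radius)
  }
  if (!is.null(cfg$conformation)) {
    cc <- cfg$conformation
    topo <- readStructure(cc$topology)
    fi <- if (is.null(cc$frame_interval)) 1 else cc$frame_interval
    traj <- readTrajectory(cc$trajectory, topo, frameInterval = fi)
    ref <- if (is.null(cc$reference)) NULL else readStructure(cc$reference)
    ts <- trajectoryTimeSeries(
      traj, reference = ref,
      sasaPoints = if (is.null(cc$sasa_points)) 120L else cc$sasa_points,
      hbond = if (is.null(cc$hbond)) TRUE else cc$hbond)
    cutoff <- if (is.null(cc$cluster_cutoff)) 0.2 else cc$cluster_cutoff
    cl <- dauraCluster(traj, cutoff = cutoff)
    discard <- if (is.null(cc$discard_ps)) 0 else cc$discard_ps
    rep <- representativeFrame(traj, discardPs = discard, cutoff = cutoff)
    out$conformation <- list(
      time_series = ts,
      clusters = list(sizes = cl$clusterSizes,
                      centroid_frames = cl$centroidFrames,
                      cutoff_nm = cl$cutoff),
      representative_frame = rep)
  }
  if (!is.null(cfg$msquant)) {
    m <- cfg$msquant
    t <- readPeakTable(m$peak_table)
    out$msquant <- reductionTable(
      t, sample = if (is.null(m$sample)) "treated" else m$sample,
      residueOffset = if (is.null(m$residue_offset)) 0 else
        m$residue_offset)
  }
  if (length(out) == 0) stop("report config has no recognised sections")
  out <- out[order(names(out))]
  writeLines(as.character(jsonlite::toJSON(out, auto_unbox = TRUE,
                                           digits = NA, pretty = TRUE,
                                           dataframe = "rows")),
             outFile)
  ok <- TRUE
  invisible(out)
}
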