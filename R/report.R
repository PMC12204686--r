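# Combined report: runs the comparative analysis stages whose inputs are
# present in the configuration and writes a deterministic JSON bundle.

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value` (or `key=value`); blank lines and lines
#' starting with `#` are ignored. Values are kept as strings; numeric-looking
#' values are converted. Multi-valued keys use commas (e.g. `group_a = A,B`).
#'
#' @param path configuration file path.
#' @return named list.
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(kv) != 3L) stop("bad config line: ", ln)
    key <- trimws(kv[2]); val <- trimws(kv[3])
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    cfg[[key]] <- if (!anyNA(nums)) nums else parts
  }
  cfg
}

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  path
}

#' Run the combined comparative analysis
#'
#' Executes every stage whose inputs appear in `config` and writes one JSON
#' file per stage plus a `report.json` manifest into `config$out_dir`.
#' Recognised keys: `structure` (path), `group_a`, `group_b` (chain ids) for
#' the interface and contact stages; `tunnel_start`, `tunnel_end`
#' (xyz anchors) for the tunnel, enrichment and enclosure stages; `msa`
#' (path) and `msa_ref` for conservation; `traj` (XYZ/PDB paths),
#' `traj_dt`, `ligand_selection`, `protein_selection` for trajectory
#' metrics; `lengths_csv` for length statistics; plus the threshold keys
#' `probe`, `points`, `sb_cutoff`, `hb_dmax`, `grid`, `margin`,
#' `escape_dist`, `sustain`, `adherence_cutoff`, `alpha` and `seed`. All
#' thresholds default to the module defaults and the full configuration is
#' recorded verbatim in the manifest, so a rerun with the same config and
#' inputs is byte-identical (no timestamps are written).
#'
#' @param config named list or path to a key=value file ([readRunConfig()]).
#' @return list (the report bundle), invisibly; files under `config$out_dir`.
#' @export
runReport <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  outDir <- config$out_dir %||% "."
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  bundle <- list(config = config, stages = character(0))
  fail <- function(stage, err) {
    manifest <- list(failed_stage = stage, error = conditionMessage(err),
                     config = config)
    .writeJson(manifest, file.path(outDir, "error_manifest.json"))
    stop("stage '", stage, "' failed: ", conditionMessage(err))
  }
  need <- function(path, what) {
    if (!file.exists(path)) stop(what, " input not found: ", path, call. = FALSE)
    path
  }
  probe <- config$probe %||% 1.4
  npts <- as.integer(config$points %||% 960L)

  structure <- NULL
  if (!is.null(config$structure)) {
    structure <- tryCatch(readStructure(need(config$structure, "structure")),
                          error = function(e) fail("load_structure", e))
  }

  if (!is.null(structure) && !is.null(config$group_a) && !is.null(config$group_b)) {
    tryCatch({
      ga <- as.character(config$group_a); gb <- as.character(config$group_b)
      bsa <- buriedSurfaceArea(structure, ga, gb, probeRadius = probe,
                               nPoints = npts, details = TRUE)
      bundle$interfaces <- bsa
      .writeJson(bsa, file.path(outDir, "interfaces.json"))
      sb <- findSaltBridges(structure, ga, gb,
                            cutoff = config$sb_cutoff %||% 4.0)
      hb <- findHbonds(structure, ga, gb, dMax = config$hb_dmax %||% 3.5)
      contacts <- list(
        saltBridges = sb, hbonds = hb,
        nSaltBridgePairs = uniqueResiduePairs(sb),
        nHbondPairs = uniqueResiduePairs(hb))
      bundle$contacts <- contacts
      utils::write.table(rbind(sb, hb), file.path(outDir, "contacts.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      .writeJson(contacts[c("nSaltBridgePairs", "nHbondPairs")],
                 file.path(outDir, "contacts_summary.json"))
      bundle$stages <- c(bundle$stages, "interfaces", "contacts")
    }, error = function(e) fail("interfaces/contacts", e))
  }

  if (!is.null(structure) && !is.null(config$tunnel_start) && !is.null(config$tunnel_end)) {
    tryCatch({
      tun <- findTunnel(structure, config$tunnel_start, config$tunnel_end,
                        gridSpacing = config$grid %||% 0.6, probeRadius = probe)
      tj <- list(algorithm = "grid-probe", found = tunnelFound(tun))
      if (tunnelFound(tun)) {
        lining <- liningResidues(structure, tun, margin = config$margin %||% 3.0)
        wp <- widestPoint(tun)
        encl <- enclosureProfile(structure, tun, probeRadius = probe)
        chan <- aaComposition(lining, structure)
        prot <- proteinComposition(structure)
        enr <- log2Enrichment(chan, prot, alpha = config$alpha %||% 0.5)
        tj <- c(tj, list(
          length = tunnelLength(tun),
          centerline = unname(apply(tunnelCenterline(tun), 1, function(r) round(r, 4), simplify = FALSE)),
          radii = round(tunnelRadii(tun), 4),
          widestIndex = wp$index, widestRadius = wp$radius,
          enclosure = encl,
          fractionEnclosed = mean(encl == "enclosed"),
          liningResidues = lining,
          log2Enrichment = as.list(log2FoldChange(enr))))
        bundle$enrichment <- as.list(log2FoldChange(enr))
      }
      bundle$tunnel <- tj[setdiff(names(tj), "centerline")]
      .writeJson(tj, file.path(outDir, "tunnel.json"))
      bundle$stages <- c(bundle$stages, "tunnel")
    }, error = function(e) fail("tunnel", e))
  }

  if (!is.null(config$msa)) {
    tryCatch({
      msa <- readMsa(need(config$msa, "msa"), ref = config$msa_ref %||% 1L)
      cons <- columnConservation(msa)
      utils::write.table(cons, file.path(outDir, "conservation.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      bundle$conservation <- cons
      bundle$stages <- c(bundle$stages, "conservation")
    }, error = function(e) fail("conservation", e))
  }

  if (!is.null(config$traj)) {
    tryCatch({
      res <- lapply(as.character(config$traj), function(p) {
        tr <- readTrajectory(need(p, "trajectory"), dt = config$traj_dt %||% 0.1,
                             ligandSelection = config$ligand_selection %||% "element:O",
                             proteinSelection = config$protein_selection %||% "element:C")
        r <- residenceTime(tr, escapeDistance = config$escape_dist %||% 10.0,
                           sustainFrames = config$sustain %||% 5L)
        list(file = p, time = residenceTimeNs(r), censored = isCensored(r),
             escapeFrame = if (isCensored(r)) NULL else escapeFrame(r))
      })
      times <- lapply(res, function(r)
        new("ResidenceResult", time = r$time, censored = r$censored,
            escapeFrame = if (is.null(r$escapeFrame)) NA_integer_ else as.integer(r$escapeFrame)))
      ens <- meanResidence(times)
      traj <- list(perTrajectory = res, ensemble = ens,
                   escapeDistance = config$escape_dist %||% 10.0,
                   sustainFrames = config$sustain %||% 5L)
      bundle$trajectories <- traj
      .writeJson(traj, file.path(outDir, "trajectories.json"))
      bundle$stages <- c(bundle$stages, "trajectories")
    }, error = function(e) fail("trajectories", e))
  }

  if (!is.null(config$lengths_csv)) {
    tryCatch({
      data <- readLengthCsv(need(config$lengths_csv, "lengths"))
      summ <- lengthSummary(data)
      tab <- lengthTable(data)
      groups <- sort(unique(tab$group))
      tests <- list()
      if (length(groups) >= 2L) {
        for (i in seq_len(length(groups) - 1L)) for (j in (i + 1L):length(groups)) {
          mw <- mannWhitneyU(tab$length_nm[tab$group == groups[i]],
                             tab$length_nm[tab$group == groups[j]])
          tests[[paste(groups[i], groups[j], sep = "_vs_")]] <-
            list(U = uStatistic(mw), p = pValue(mw), method = mw@method)
        }
      }
      stats <- list(summary = summ, mannWhitney = tests)
      bundle$lengths <- stats
      .writeJson(stats, file.path(outDir, "lengths.json"))
      bundle$stages <- c(bundle$stages, "lengths")
    }, error = function(e) fail("lengths", e))
  }

  .writeJson(list(stages = bundle$stages, config = config),
             file.path(outDir, "report.json"))
  invisible(bundle)
}
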