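#' Aggregate occupancy tables across replicates
#'
#' Residue pairs are united across replicates; a pair missing from one
#' replicate's table counts as occupancy 0 there (it never bonded in that
#' run), so means and spreads are over the full replicate count.
#'
#' @param tables list of \code{\link{occupancy}} tables (one per replicate)
#' @param condition condition label stored on the result
#' @return data.frame with per-pair \code{mean_occupancy} and \code{sd}.
#' @export
aggregate_occupancy <- function(tables, condition = NA_character_) {
  if (length(tables) == 0L) stop("no tables to aggregate", call. = FALSE)
  pairs <- unique(do.call(rbind, lapply(tables, function(t)
    t[, c("res_a", "res_b")])))
  if (is.null(pairs) || nrow(pairs) == 0L)
    return(data.frame(res_a = character(0), res_b = character(0),
                      condition = character(0), mean_occupancy = numeric(0),
                      sd = numeric(0), stringsAsFactors = FALSE))
  vals <- sapply(tables, function(t) {
    key <- paste(t$res_a, t$res_b)
    v <- t$occupancy[match(paste(pairs$res_a, pairs$res_b), key)]
    ifelse(is.na(v), 0, v)
  })
  vals <- matrix(vals, nrow = nrow(pairs))
  out <- data.frame(res_a = pairs$res_a, res_b = pairs$res_b,
                    condition = condition,
                    mean_occupancy = rowMeans(vals),
                    sd = apply(vals, 1, function(v)
                      if (length(v) > 1L) stats::sd(v) else 0),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_occupancy), ]
  rownames(out) <- NULL
  out
}

#' Equilibrium-campaign analysis
#'
#' Mirrors the equilibrium comparison of two (or more) molecular systems:
#' per system, replicate-aggregated C-alpha RMSD, residue-pair occupancy
#' table, per-frame interface H-bond count (N_HB), dissociation probability
#' fD from the per-replicate occupancies, and optionally buried SASA and
#' interaction energy; plus cross-system comparison p-values (unpaired
#' two-tailed Student's t on the replicate values). Replicate aggregation is
#' mean +/- SD, the convention for equilibrium comparisons.
#'
#' @param systems named list; each element is a list with components
#'   \code{trajectories} (list of \code{md_trajectory} replicates),
#'   \code{selA}, \code{selB} (interface selections) and optionally
#'   \code{rmsd_sel} (superposition set; defaults to \code{selA}+\code{selB})
#' @param criteria \code{\link{hbond_criteria}}
#' @param compute_sasa,compute_energy include buried SASA / interaction
#'   energy (energy requires attached nonbonded parameters)
#' @param sasa_stride frame stride for the SASA series
#' @return object of class \code{equilibrium_report}.
#' @export
run_equilibrium_analysis <- function(systems, criteria = hbond_criteria(),
                                     compute_sasa = FALSE,
                                     compute_energy = FALSE,
                                     sasa_stride = 10L) {
  if (length(systems) < 1L) stop("need at least one system", call. = FALSE)
  if (is.null(names(systems)))
    stop("systems must be a named list", call. = FALSE)
  per_system <- list()
  for (nm in names(systems)) {
    sys <- systems[[nm]]
    if (length(sys$trajectories) < 1L)
      stop("system '", nm, "' has no trajectories", call. = FALSE)
    selA <- sys$selA; selB <- sys$selB
    .mb_check_selection(selA); .mb_check_selection(selB)
    rmsd_sel <- sys$rmsd_sel
    if (is.null(rmsd_sel))
      rmsd_sel <- structure(list(structure = selA$structure,
                                 indices = c(selA$indices, selB$indices),
                                 label = "interface"),
                            class = "md_selection")
    occ_tabs <- list(); rmsd_mean <- nhb_mean <- fd <- numeric(0)
    sasa_mean <- e_mean <- numeric(0)
    for (k in seq_along(sys$trajectories)) {
      tr <- sys$trajectories[[k]]
      occ_tabs[[k]] <- occupancy(tr, selA, selB, criteria,
                                 condition = nm)
      rmsd_mean[k] <- mean(rmsd_series(tr, rmsd_sel))
      nhb <- hbond_count_series(tr, selA, selB, criteria)
      nhb_mean[k] <- mean(nhb)
      fd[k] <- dissociation_probability(occ_tabs[[k]]$occupancy)
      if (compute_sasa)
        sasa_mean[k] <- mean(buried_sasa_series(tr, selA, selB,
                                                stride = sasa_stride)$buried_sasa)
      if (compute_energy)
        e_mean[k] <- mean(interaction_energy_series(tr, selA, selB)$total)
    }
    single <- length(sys$trajectories) == 1L
    agg <- function(v) c(mean = mean(v),
                         sd = if (length(v) > 1L) stats::sd(v) else 0)
    per_system[[nm]] <- list(
      occupancy = aggregate_occupancy(occ_tabs, nm),
      replicate_fd = fd, replicate_nhb = nhb_mean,
      replicate_rmsd = rmsd_mean,
      rmsd = agg(rmsd_mean), n_hb = agg(nhb_mean), fd = agg(fd),
      buried_sasa = if (compute_sasa) agg(sasa_mean),
      energy = if (compute_energy) agg(e_mean),
      single_replicate = single)
  }
  comparisons <- NULL
  nms <- names(systems)
  if (length(nms) >= 2L) {
    cmp <- list()
    for (i in seq_along(nms)) for (j in seq_along(nms)) if (i < j) {
      a <- per_system[[nms[i]]]; b <- per_system[[nms[j]]]
      p_fd <- p_nhb <- NA_real_
      if (length(a$replicate_fd) >= 2L && length(b$replicate_fd) >= 2L) {
        p_fd <- compare_replicates(a$replicate_fd, b$replicate_fd, "t")
        p_nhb <- compare_replicates(a$replicate_nhb, b$replicate_nhb, "t")
      }
      cmp[[length(cmp) + 1L]] <- data.frame(
        system_a = nms[i], system_b = nms[j], p_fd = p_fd, p_nhb = p_nhb,
        stringsAsFactors = FALSE)
    }
    comparisons <- do.call(rbind, cmp)
  }
  structure(list(systems = per_system, comparisons = comparisons),
            class = "equilibrium_report")
}

#' @export
print.equilibrium_report <- function(x, ...) {
  for (nm in names(x$systems)) {
    s <- x$systems[[nm]]
    cat(sprintf("%s: RMSD %.2f +/- %.2f A | N_HB %.2f +/- %.2f | fD %.4g +/- %.2g\n",
                nm, s$rmsd["mean"], s$rmsd["sd"], s$n_hb["mean"],
                s$n_hb["sd"], s$fd["mean"], s$fd["sd"]))
    if (s$single_replicate)
      cat("  (single replicate: SD columns are 0 by construction)\n")
  }
  if (!is.null(x$comparisons)) print(x$comparisons)
  invisible(x)
}

#' Turn an equilibrium report into writable tables
#'
#' @param report an \code{equilibrium_report}
#' @return named list of data.frames suitable for \code{\link{write_report}}.
#' @export
equilibrium_tables <- function(report) {
  summ <- do.call(rbind, lapply(names(report$systems), function(nm) {
    s <- report$systems[[nm]]
    data.frame(system = nm, rmsd_mean = s$rmsd["mean"],
               rmsd_sd = s$rmsd["sd"],
               n_hb_mean = s$n_hb["mean"], n_hb_sd = s$n_hb["sd"],
               fd_mean = s$fd["mean"], fd_sd = s$fd["sd"],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  occ <- do.call(rbind, lapply(report$systems, `[[`, "occupancy"))
  rownames(occ) <- NULL
  out <- list(summary = summ, occupancy = occ)
  if (!is.null(report$comparisons)) out$comparisons <- report$comparisons
  out
}

#' Force-clamp-campaign analysis
#'
#' Builds force-response profiles over the clamp force grid: per-frame
#' H-bond count N_HB, dissociation probability fD (from each replicate's
#' pair occupancies), optionally interaction energy E, mass-center distance
#' (DMC) and cross-angle kappa; locates biphasic thresholds; fits a Gaussian
#' to the N_HB frequency histogram per force; and produces the per-pair
#' thermograph (residue pair x force mean occupancy) with a force-response
#' mode label per pair. Profiles aggregate replicates as mean +/- SE.
#'
#' @param runs list over force levels; each element a list with
#'   \code{force} (pN) and \code{trajectories} (replicates)
#' @param selA,selB interface selections
#' @param criteria \code{\link{hbond_criteria}}
#' @param loops optional list(loop1, loop2) of selections for the DMC profile
#' @param strands optional list(strandA, strandB) selections for kappa
#' @param compute_energy include the interaction-energy profile
#' @param epsilon dead band for mode classification, occupancy units
#' @return object of class \code{clamp_report}.
#' @export
run_force_clamp_analysis <- function(runs, selA, selB,
                                     criteria = hbond_criteria(),
                                     loops = NULL, strands = NULL,
                                     compute_energy = FALSE,
                                     epsilon = 0.05) {
  if (length(runs) < 3L) stop("need at least 3 force levels", call. = FALSE)
  forces <- vapply(runs, `[[`, numeric(1), "force")
  if (any(diff(forces) <= 0))
    stop("force grid must be strictly increasing", call. = FALSE)
  nhb_rep <- fd_rep <- e_rep <- dmc_rep <- kap_rep <- list()
  occ_by_force <- list()
  gauss <- list()
  for (k in seq_along(runs)) {
    trs <- runs[[k]]$trajectories
    if (length(trs) < 1L) stop("force level ", forces[k],
                               " has no trajectories", call. = FALSE)
    nhb_all <- integer(0)
    nhb_rep[[k]] <- fd_rep[[k]] <- e_rep[[k]] <- numeric(length(trs))
    dmc_rep[[k]] <- kap_rep[[k]] <- numeric(length(trs))
    tabs <- list()
    for (r in seq_along(trs)) {
      tr <- trs[[r]]
      nhb <- hbond_count_series(tr, selA, selB, criteria)
      nhb_all <- c(nhb_all, nhb)
      nhb_rep[[k]][r] <- mean(nhb)
      tabs[[r]] <- occupancy(tr, selA, selB, criteria,
                             condition = as.character(forces[k]))
      fd_rep[[k]][r] <- dissociation_probability(tabs[[r]]$occupancy)
      if (compute_energy)
        e_rep[[k]][r] <- mean(interaction_energy_series(tr, selA, selB)$total)
      if (!is.null(loops))
        dmc_rep[[k]][r] <- mean(dmc_series(tr, loops[[1]], loops[[2]]))
      if (!is.null(strands))
        kap_rep[[k]][r] <- mean(cross_angle_series(tr, strands[[1]],
                                                   strands[[2]]))
    }
    occ_by_force[[k]] <- aggregate_occupancy(tabs,
                                             as.character(forces[k]))
    gauss[[k]] <- tryCatch(fit_gaussian(nhb_all), error = function(e) NULL)
  }
  profiles <- list(N_HB = force_profile("N_HB", forces, nhb_rep),
                   fD = force_profile("fD", forces, fd_rep))
  if (compute_energy) profiles$E <- force_profile("E", forces, e_rep)
  if (!is.null(loops)) profiles$DMC <- force_profile("DMC", forces, dmc_rep)
  if (!is.null(strands))
    profiles$kappa <- force_profile("kappa", forces, kap_rep)
  thresholds <- lapply(profiles, biphasic_threshold)
  # thermograph: pair x force mean occupancy + mode
  all_pairs <- unique(do.call(rbind, lapply(occ_by_force, function(t)
    t[, c("res_a", "res_b")])))
  thermo <- NULL
  if (!is.null(all_pairs) && nrow(all_pairs)) {
    occ_mat <- sapply(occ_by_force, function(t) {
      v <- t$mean_occupancy[match(paste(all_pairs$res_a, all_pairs$res_b),
                                  paste(t$res_a, t$res_b))]
      ifelse(is.na(v), 0, v)
    })
    occ_mat <- matrix(occ_mat, nrow = nrow(all_pairs))
    colnames(occ_mat) <- paste0("F", forces)
    modes <- apply(occ_mat, 1, function(o)
      classify_mode(o, epsilon)$mode)
    thermo <- cbind(all_pairs, as.data.frame(occ_mat),
                    data.frame(mode = modes, stringsAsFactors = FALSE))
    rownames(thermo) <- NULL
  }
  structure(list(force_grid = forces, profiles = profiles,
                 thresholds = thresholds, thermograph = thermo,
                 gaussian_fits = gauss),
            class = "clamp_report")
}

#' @export
print.clamp_report <- function(x, ...) {
  cat("force-clamp report over", length(x$force_grid), "forces (",
      paste(x$force_grid, collapse = ", "), "pN )\n")
  for (nm in names(x$profiles)) {
    th <- x$thresholds[[nm]]
    cat(sprintf("  %s: %s\n", nm,
                if (th$biphasic)
                  sprintf("biphasic threshold %g pN (%s)", th$threshold,
                          th$direction)
                else if (nrow(th$extrema) == 0L) "monotone"
                else "non-biphasic"))
  }
  if (!is.null(x$thermograph))
    cat("  thermograph:", nrow(x$thermograph), "residue pairs\n")
  invisible(x)
}

#' Force-ramp-campaign analysis
#'
#' Per-frame series mirroring a constant-velocity pulling run: force-time
#' (from the trace), interface H-bond count, C-alpha RMSD, steered-fixed
#' distance, strided buried SASA, and the rupture force (smoothed force
#' maximum before the H-bond count first reaches zero).
#'
#' @param trajectory the ramp \code{md_trajectory}
#' @param trace a \code{\link{force_trace}} aligned frame-by-frame to the
#'   trajectory
#' @param selA,selB interface selections
#' @param steered_atom,fixed_atom atom indices for the pull-distance series
#' @param criteria \code{\link{hbond_criteria}}
#' @param sasa_stride stride for the buried-SASA series (0 skips SASA)
#' @param window smoothing window for rupture detection
#' @return object of class \code{ramp_report}.
#' @export
run_ramp_analysis <- function(trajectory, trace, selA, selB,
                              steered_atom, fixed_atom,
                              criteria = hbond_criteria(),
                              sasa_stride = 10L, window = 11L) {
  if (nrow(trace) != mb_n_frames(trajectory))
    stop("force trace length (", nrow(trace), ") does not match the ",
         "trajectory (", mb_n_frames(trajectory), " frames)", call. = FALSE)
  nhb <- hbond_count_series(trajectory, selA, selB, criteria)
  trace2 <- force_trace(trace$time_ns, trace$force_pn, nhb)
  rupture <- rupture_force(trace2, window)
  rmsd_sel <- structure(list(structure = selA$structure,
                             indices = c(selA$indices, selB$indices),
                             label = "interface"), class = "md_selection")
  series <- data.frame(time_ns = trace$time_ns, force_pn = trace$force_pn,
                       n_hb = nhb,
                       rmsd = rmsd_series(trajectory, rmsd_sel),
                       pull_distance = pull_distance_series(trajectory,
                                                            steered_atom,
                                                            fixed_atom))
  sasa_series <- if (sasa_stride > 0L)
    buried_sasa_series(trajectory, selA, selB, stride = sasa_stride)
  structure(list(series = series, sasa = sasa_series, rupture = rupture),
            class = "ramp_report")
}

#' @export
print.ramp_report <- function(x, ...) {
  print(x$rupture)
  cat("series over", nrow(x$series), "frames; final N_HB =",
      x$series$n_hb[nrow(x$series)], "\n")
  invisible(x)
}

# ---- YAML configuration -------------------------------------------------

#' Load a generator configuration from YAML
#'
#' Expected keys mirror \code{\link{generator_config}}; bonds are listed
#' under \code{bond_specs} with \code{donor: [chain, resno]},
#' \code{acceptor: [chain, resno]}, \code{mode} and curve parameters.
#'
#' @param path YAML file
#' @return a \code{\link{generator_config}}.
#' @export
load_generator_config <- function(path) {
  y <- yaml::read_yaml(path)
  req <- c("n_residues_per_chain", "bond_specs", "n_frames")
  miss <- setdiff(req, names(y))
  if (length(miss))
    stop("generator config missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  specs <- lapply(y$bond_specs, function(b)
    bond_spec(donor = b$donor, acceptor = b$acceptor,
              mode = if (is.null(b$mode)) "steady" else b$mode,
              baseline = if (is.null(b$baseline)) 0.5 else b$baseline,
              amplitude = if (is.null(b$amplitude)) 0.4 else
                unlist(b$amplitude),
              center = if (is.null(b$center)) 50 else unlist(b$center),
              width = if (is.null(b$width)) 20 else unlist(b$width)))
  args <- list(n_residues_per_chain = y$n_residues_per_chain,
               bond_specs = specs, n_frames = y$n_frames)
  for (k in c("force_grid", "seed", "bound_distance", "bound_deviation",
              "unbound_distance", "jitter", "dt_ns", "markov_rho"))
    if (!is.null(y[[k]])) args[[k]] <- unlist(y[[k]])
  if (!is.null(y$resno_start))
    args$resno_start <- unlist(y$resno_start)
  do.call(generator_config, args)
}

#' Load an analysis run configuration from YAML
#'
#' Validates and returns the raw configuration list: system label, chain and
#' residue-range selections (interface sides, loops, strands, steered and
#' fixed atoms), force grid, criteria overrides and output directory. Chain
#' mapping is explicit because crystal-structure chain identifiers vary
#' between depositions.
#'
#' @param path YAML file
#' @return named list of class \code{run_config}.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$selections) || is.null(y$selections$interface))
    stop("run config needs selections$interface with sides a and b",
         call. = FALSE)
  iface <- y$selections$interface
  for (side in c("a", "b"))
    if (is.null(iface[[side]]$chain) || is.null(iface[[side]]$residues))
      stop("interface side '", side, "' needs chain + residues [lo, hi]",
           call. = FALSE)
  structure(y, class = c("run_config", "list"))
}

#' Resolve a run-config selection block against a structure
#'
#' @param structure an \code{md_structure}
#' @param block list with \code{chain} and \code{residues} \code{[lo, hi]}
#' @param label selection label
#' @return an \code{md_selection}.
#' @export
resolve_selection <- function(structure, block, label = NULL) {
  select_residues(structure, block$chain,
                  c(block$residues[[1]], block$residues[[2]]), label)
}
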