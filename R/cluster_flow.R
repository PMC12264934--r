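# Metastable-state analysis across replicas: frame selection, featurisation
# (fingerprint + dCOM + ligand RMSD), contact-based clustering, cluster
# graphs with directed transition counts and net flows, and
# loop-flexibility profiles binned over the path progress S.

#' Select analysis frames at a fixed interval up to translocation + margin
#'
#' Frames are taken every `interval` ps from the start until the first
#' ligand-RMSD crossing of `rmsd_stop`, plus an `extra` margin beyond that
#' point, truncated at the trajectory end. A trajectory that never crosses
#' contributes all its frames at the interval.
#'
#' @param traj A `trajectory3d`.
#' @param interval Sampling interval in ps (default 100).
#' @param rmsd_stop Ligand RMSD stop cutoff in Angstrom (default 14).
#' @param extra Extra time beyond the crossing in ps (default 5000, i.e.
#'   5 ns).
#' @param ligand_sel,fit_sel Passed to [ligand_rmsd_series()].
#' @return Integer frame indices (1-based).
#' @export
select_analysis_frames <- function(traj, interval = 100, rmsd_stop = 14,
                                   extra = 5000, ligand_sel = NULL,
                                   fit_sel = NULL) {
  stride <- max(1L, round(interval / traj$dt))
  idx <- seq(1L, n_frames(traj), by = stride)
  ev <- first_crossing(ligand_rmsd_series(traj, ligand_sel, fit_sel),
                       cutoff = rmsd_stop)
  if (!ev$censored) {
    t_end <- ev$time + extra
    idx <- idx[(idx - 1L) * traj$dt <= t_end]
  }
  idx
}

#' Featurise analysis frames
#'
#' Per frame: the interaction fingerprint, dCOM (distance between the
#' instantaneous and initial ligand centre of mass, no drift correction by
#' default), and the ligand RMSD from the start.
#'
#' @param traj A `trajectory3d` with typed atoms.
#' @param frames Frame indices (default: all).
#' @param ligand_sel Ligand selection (default from flags).
#' @param fit_sel Optional receptor fit selection; when given, both dCOM
#'   and RMSD are computed after superposition (drift-corrected variant).
#' @param replica Replica id attached to every row.
#' @param config Fingerprint geometry ([ifp_config()]).
#' @return Object of class `frame_features`: data.frame (replica, frame,
#'   time, dcom, rmsd) with the fingerprint list as attribute `ifps`.
#' @export
featurize <- function(traj, frames = seq_len(n_frames(traj)),
                      ligand_sel = NULL, fit_sel = NULL, replica = 1L,
                      config = ifp_config()) {
  if (is.null(ligand_sel)) ligand_sel <- select_atoms(traj, ligand = TRUE)
  li <- sel_indices(ligand_sel)
  ref <- get_frame(traj, 1L)
  fidx <- if (is.null(fit_sel)) NULL else sel_indices(fit_sel)
  com0 <- centre_of_mass(ref, li)
  rms <- rmsd_series(traj, reference = 1L, fit_sel = fit_sel,
                     measure_sel = ligand_sel)
  rows <- lapply(frames, function(i) {
    x <- get_frame(traj, i)
    if (!is.null(fidx)) {
      fit <- kabsch_superpose(x[fidx, , drop = FALSE], ref[fidx, , drop = FALSE])
      x <- apply_transform(x, fit)
    }
    data.frame(replica = replica, frame = i, time = (i - 1L) * traj$dt,
               dcom = sqrt(sum((centre_of_mass(x, li) - com0)^2)),
               rmsd = rms[i])
  })
  out <- do.call(rbind, rows)
  attr(out, "ifps") <- lapply(frames, function(i) {
    compute_ifp(traj, ligand_sel, config = config, frame = i)
  })
  class(out) <- c("frame_features", class(out))
  out
}

#' Combine featurised replicas
#' @param ... `frame_features` objects.
#' @return A single `frame_features`.
#' @export
bind_features <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) &&
      !inherits(parts[[1L]], "frame_features")) parts <- parts[[1L]]
  out <- do.call(rbind, lapply(parts, function(p) as.data.frame(p)))
  attr(out, "ifps") <- do.call(c, lapply(parts, attr, "ifps"))
  class(out) <- c("frame_features", class(out))
  out
}

#' Cluster frames by their interaction patterns
#'
#' Average-linkage agglomerative clustering on the Tanimoto distance
#' between frame fingerprints (specific features plus nonspecific contacts,
#' so frames without specific interactions still separate), cut at a fixed
#' distance. Cluster labels are relabelled in order of increasing mean
#' dCOM, so cluster 1 is the bound state. The procedure is deterministic;
#' `seed` is accepted for interface uniformity.
#'
#' @param features A `frame_features` object.
#' @param cut Cophenetic cut distance (default 0.4).
#' @param method Linkage (default "average").
#' @param seed Unused (deterministic); kept for interface stability.
#' @return Integer cluster assignment per row of `features`.
#' @export
cluster_frames <- function(features, cut = 0.4, method = "average",
                           seed = NULL) {
  ifps <- attr(features, "ifps")
  n <- length(ifps)
  if (n == 0L) stop("empty input")
  if (n == 1L) return(1L)
  keys <- lapply(ifps, function(f) {
    c(f$features, paste0("contact.", f$contacts))
  })
  dm <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dm[i, j] <- dm[j, i] <- tanimoto_distance(keys[[i]], keys[[j]])
    }
  }
  if (all(dm == 0)) return(rep(1L, n))
  hc <- hclust(as.dist(dm), method = method)
  # guard against tiny non-monotone height wiggles from tied distances
  hc$height <- cummax(hc$height)
  raw <- cutree(hc, h = cut)
  mean_dcom <- tapply(features$dcom, raw, mean)
  relabel <- match(raw, as.integer(names(sort(mean_dcom))))
  as.integer(relabel)
}

#' Build the cluster graph with transition counts and net flows
#'
#' Transitions are counted between consecutive analysis frames within each
#' replica; counts are aggregated across replicas, then the net flow
#' between two clusters is `|count(i->j) - count(j->i)|`.
#'
#' @param assignments Integer cluster per frame (aligned with `features`).
#' @param features The `frame_features` the assignments refer to (supplies
#'   replica ids, frame order, dCOM, RMSD and fingerprints).
#' @return Object of class `cluster_graph`: `nodes` data.frame (cluster,
#'   population, mean_dcom, mean_rmsd), `edges` data.frame (from, to,
#'   count, net_flow, direction), and `ifp_freq` (per-cluster feature
#'   frequency tables).
#' @export
build_cluster_graph <- function(assignments, features) {
  stopifnot(length(assignments) == nrow(features))
  nodes <- data.frame(
    cluster = sort(unique(assignments)),
    population = as.integer(table(assignments)),
    mean_dcom = as.numeric(tapply(features$dcom, assignments, mean)),
    mean_rmsd = as.numeric(tapply(features$rmsd, assignments, mean)))
  counts <- list()
  for (rep in unique(features$replica)) {
    ord <- order(features$frame[features$replica == rep])
    a <- assignments[features$replica == rep][ord]
    if (length(a) < 2L) next
    from <- a[-length(a)]; to <- a[-1L]
    keep <- from != to
    for (k in which(keep)) {
      key <- paste(from[k], to[k], sep = "->")
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  if (length(counts)) {
    parts <- strsplit(names(counts), "->", fixed = TRUE)
    edges <- data.frame(from = as.integer(vapply(parts, `[`, "", 1L)),
                        to = as.integer(vapply(parts, `[`, "", 2L)),
                        count = as.integer(unlist(counts)))
    pair_id <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    edges$net_flow <- NA_integer_
    edges$direction <- NA_integer_
    for (p in unique(pair_id)) {
      rows <- which(pair_id == p)
      fwd <- edges$count[rows[1L]]
      bwd <- if (length(rows) > 1L) edges$count[rows[2L]] else 0L
      nf <- abs(fwd - bwd)
      edges$net_flow[rows] <- nf
      edges$direction[rows] <- if (fwd >= bwd) edges$to[rows[1L]] else edges$from[rows[1L]]
    }
  } else {
    edges <- data.frame(from = integer(), to = integer(), count = integer(),
                        net_flow = integer(), direction = integer())
  }
  ifps <- attr(features, "ifps")
  ifp_freq <- lapply(nodes$cluster, function(cl) {
    members <- which(assignments == cl)
    feats <- unlist(lapply(ifps[members], `[[`, "features"))
    if (!length(feats)) return(numeric())
    sort(table(feats) / length(members), decreasing = TRUE)
  })
  names(ifp_freq) <- nodes$cluster
  structure(list(nodes = nodes, edges = edges, ifp_freq = ifp_freq),
            class = "cluster_graph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cluster_graph <- function(x, ...) {
  cat(sprintf("cluster_graph: %d clusters, %d directed edges\n",
              nrow(x$nodes), nrow(x$edges)))
  print(x$nodes)
  invisible(x)
}

#' Loop flexibility binned over the path progress S
#'
#' Assigns frames to S bins (default edges at 4 and 16: orthosteric,
#' transition, vestibular) and reports the spread of the loop heavy-atom
#' conformation per bin: each frame's loop RMSD from the mean loop
#' structure of its bin, after superposition on `fit_sel` when given.
#'
#' @param traj A `trajectory3d`.
#' @param loop_sel Selection of the loop heavy atoms.
#' @param frameset A `path_frameset` over `path_sel` atoms.
#' @param path_sel Selection mapping trajectory atoms onto the frameset
#'   rows (default: all atoms).
#' @param breaks S bin edges (default `c(-Inf, 4, 16, Inf)`).
#' @param fit_sel Optional superposition selection.
#' @return data.frame (bin, n, mean_rmsd, sd_rmsd) with per-frame values as
#'   attribute `values`; empty bins are kept with n = 0 and NA spread.
#' @export
loop_flexibility_by_s <- function(traj, loop_sel, frameset, path_sel = NULL,
                                  breaks = c(-Inf, 4, 16, Inf),
                                  fit_sel = NULL) {
  pidx <- if (is.null(path_sel)) seq_len(n_atoms(traj)) else sel_indices(path_sel)
  lidx <- sel_indices(loop_sel)
  nf <- n_frames(traj)
  s_vals <- vapply(seq_len(nf), function(i) {
    path_cvs(get_frame(traj, i)[pidx, , drop = FALSE], frameset)$S
  }, numeric(1))
  bins <- cut(s_vals, breaks = breaks, include.lowest = TRUE)
  frames <- lapply(seq_len(nf), function(i) {
    x <- get_frame(traj, i)
    if (!is.null(fit_sel)) {
      fidx <- sel_indices(fit_sel)
      ref <- get_frame(traj, 1L)
      fit <- kabsch_superpose(x[fidx, , drop = FALSE], ref[fidx, , drop = FALSE])
      x <- apply_transform(x, fit)
    }
    x[lidx, , drop = FALSE]
  })
  per_frame <- data.frame(frame = seq_len(nf), S = s_vals, bin = bins,
                          rmsd = NA_real_)
  for (b in levels(bins)) {
    members <- which(bins == b)
    if (!length(members)) next
    mean_loop <- Reduce(`+`, frames[members]) / length(members)
    per_frame$rmsd[members] <- vapply(members, function(i) {
      sqrt(mean(rowSums((frames[[i]] - mean_loop)^2)))
    }, numeric(1))
  }
  out <- data.frame(
    bin = levels(bins),
    n = as.integer(table(bins)),
    mean_rmsd = as.numeric(tapply(per_frame$rmsd, bins, mean)),
    sd_rmsd = as.numeric(tapply(per_frame$rmsd, bins, sd)))
  attr(out, "values") <- per_frame
  out
}
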