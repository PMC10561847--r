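#' Per-trial feature points for behavioral clustering
#'
#' One point per tap trial: the stimulus phase-coherence magnitude (log10
#' transformed for clustering, mirroring the logarithmic coherence axis of
#' the trial map) and the trial's mean normalized inter-tap interval.
#' Trials with fewer than 2 taps carry no interval and are excluded with a
#' warning.
#'
#' @param trials List of `tap_trial`s.
#' @param sequences Named list of `stimulus_sequence`s covering every
#'   trial's `stimulus_id`.
#' @return Data frame with `participant_id`, `stimulus_id`, `condition`,
#'   `tempo_bpm`, `mean_r`, `log10_r`, `mean_niti`, `mean_iti`.
#' @export
build_trial_points <- function(trials, sequences) {
  rows <- vector("list", length(trials))
  n_excluded <- 0L
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    if (length(tr$nitis) < 1L) {
      n_excluded <- n_excluded + 1L
      next
    }
    sq <- sequences[[tr$stimulus_id]]
    if (is.null(sq)) stop("no stimulus sequence for ", tr$stimulus_id)
    rows[[i]] <- data.frame(
      participant_id = tr$participant_id,
      stimulus_id = tr$stimulus_id,
      condition = sq$condition_label,
      tempo_bpm = sq$config$base_tempo,
      mean_r = sq$mean_r,
      log10_r = log10(sq$mean_r),
      mean_niti = mean(tr$nitis),
      mean_iti = mean(tr$itis))
  }
  if (n_excluded > 0L)
    warning(n_excluded, " trial(s) with fewer than 2 taps excluded")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' k-means clustering of trial points
#'
#' Clusters trials in the z-scored `(log10 coherence, mean nITI)` plane
#' with `k = 5` and multiple restarts, then attaches semantic cluster
#' labels via [label_clusters()] on the raw (unscaled) centroids.
#'
#' After z-scoring, the nITI axis is up-weighted (default 2) in the
#' k-means distance: the five published clusters are nITI bands (two
#' around 1, one below 0.7, one around 2, one above 2.4) that span ranges
#' of coupling, and with a factorial stimulus design the discrete
#' per-condition coherence columns would otherwise dominate the distance
#' and split clusters by condition instead of by tapping behavior.
#'
#' @param points Data frame from [build_trial_points()].
#' @param k Number of clusters (default 5).
#' @param seed Seed for the k-means restarts.
#' @param nstart Number of random restarts.
#' @param niti_weight Weight of the z-scored nITI feature relative to the
#'   z-scored log-coherence feature.
#' @return A `cluster_model` list: `kmeans` (the [stats::kmeans()] fit),
#'   `centroids` (raw-feature centroids with semantic `label`), `scale`
#'   (centers/SDs used for z-scoring), `assignment` (the input `points`
#'   plus `cluster` index and semantic `label`).
#' @export
fit_clusters <- function(points, k = 5L, seed = NULL, nstart = 25L,
                         niti_weight = 2) {
  feats <- as.matrix(points[, c("log10_r", "mean_niti")])
  if (nrow(unique(feats)) < k)
    stop("need at least ", k, " distinct points for k = ", k)
  centers <- colMeans(feats)
  sds <- apply(feats, 2, stats::sd)
  sds[sds == 0] <- 1
  w <- c(1, niti_weight)
  z <- sweep(sweep(sweep(feats, 2, centers), 2, sds, "/"), 2, w, "*")
  if (!is.null(seed)) set.seed(seed)
  km <- stats::kmeans(z, centers = k, nstart = nstart, iter.max = 100L)
  raw_centroids <- sweep(sweep(sweep(km$centers, 2, w, "/"), 2, sds, "*"),
                         2, centers, "+")
  labels <- label_clusters(raw_centroids)
  assignment <- points
  assignment$cluster <- km$cluster
  assignment$label <- labels[km$cluster]
  structure(
    list(kmeans = km,
         centroids = data.frame(raw_centroids, label = labels),
         scale = list(center = centers, sd = sds),
         assignment = assignment),
    class = "cluster_model")
}

#' Semantic labels for cluster centroids
#'
#' Applies the published cluster semantics to raw centroids in
#' `(log10 coherence, mean nITI)` space:
#' \itemize{
#'   \item nITI in `[0.8, 1.4]` ("around 1"): the highest-coherence
#'     centroid is cluster 1 (regular beat tapping under strong coupling),
#'     the rest are cluster 2 (regular tapping under weaker coupling);
#'   \item nITI below 0.7: cluster 3 (frequent tapping);
#'   \item nITI in `[1.6, 2.4]` ("around 2"): cluster 4;
#'   \item nITI above 2.4 ("more than 2"): cluster 5;
#'   \item anything else: nearest of the above rules, with a warning.
#' }
#' Band edges are configurable.
#'
#' @param centroids Matrix or data frame with columns `log10_r` and
#'   `mean_niti`, one row per centroid.
#' @param bands Named list of the nITI band edges.
#' @return Integer vector of semantic labels (1-5) per centroid row.
#' @export
label_clusters <- function(centroids,
                           bands = list(one = c(0.8, 1.4), three_max = 0.7,
                                        four = c(1.6, 2.4), five_min = 2.4)) {
  centroids <- as.data.frame(centroids)
  niti <- centroids$mean_niti
  coh <- centroids$log10_r
  labels <- integer(length(niti))
  in_one <- niti >= bands$one[1] & niti <= bands$one[2]
  labels[niti < bands$three_max] <- 3L
  labels[niti >= bands$four[1] & niti <= bands$four[2]] <- 4L
  labels[niti > bands$five_min] <- 5L
  if (any(in_one)) {
    ones <- which(in_one)
    top <- ones[which.max(coh[ones])]  # coherence tie-break for cluster 1
    labels[ones] <- 2L
    labels[top] <- 1L
  }
  if (any(labels == 0L)) {
    gaps <- which(labels == 0L)
    warning("centroid nITI outside all semantic bands for centroid(s) ",
            paste(gaps, collapse = ", "), "; nearest band used")
    for (g in gaps) {
      # nearest band by nITI distance
      dists <- c(one = min(abs(niti[g] - bands$one)),
                 three = abs(niti[g] - bands$three_max),
                 four = min(abs(niti[g] - bands$four)),
                 five = abs(niti[g] - bands$five_min))
      labels[g] <- c(one = 2L, three = 3L, four = 4L, five = 5L)[
        names(which.min(dists))]
    }
  }
  labels
}

#' Assign participants to tapping-phenotype groups
#'
#' Classifies each participant from the semantic cluster labels of their
#' trials, using the occupancy rules:
#' \itemize{
#'   \item \strong{Fast}: more than 50 percent of non-strong-condition
#'     trials in cluster 3;
#'   \item \strong{Hybrid}: cluster-3 share above 50 percent in the none
#'     condition only (not in medium or weak);
#'   \item \strong{Regular}: more than 50 percent of all trials in
#'     clusters 1 or 2;
#'   \item otherwise unclassified (`NA`), flagged.
#' }
#' The Fast and Hybrid rules are evaluated before the Regular rule: a
#' participant who taps on the beat except under vanishing coupling still
#' has a majority of trials in clusters 1-2, so the frequent-tapping rules
#' must take precedence for the published group semantics to be
#' recoverable.
#'
#' @param assignment Data frame with columns `participant_id`,
#'   `condition`, `label` (e.g. `fit_clusters()$assignment`).
#' @return A `group_assignment` data frame: `participant_id`, `group`,
#'   `prop_12` (overall clusters 1-2 share), plus per-condition cluster-3
#'   shares `c3_strong`, `c3_medium`, `c3_weak`, `c3_none`.
#' @export
assign_groups <- function(assignment) {
  needed <- c("participant_id", "condition", "label")
  if (!all(needed %in% names(assignment)))
    stop("`assignment` needs columns ", paste(needed, collapse = ", "))
  participants <- unique(assignment$participant_id)
  rows <- lapply(participants, function(pid) {
    a <- assignment[assignment$participant_id == pid, ]
    if (nrow(a) == 0L)
      return(data.frame(participant_id = pid, group = NA_character_,
                        prop_12 = NA_real_, c3_strong = NA_real_,
                        c3_medium = NA_real_, c3_weak = NA_real_,
                        c3_none = NA_real_))
    c3_share <- function(cond) {
      sub <- a[a$condition == cond, ]
      if (nrow(sub) == 0L) return(NA_real_)
      mean(sub$label == 3L)
    }
    shares <- vapply(c("strong", "medium", "weak", "none"), c3_share,
                     numeric(1))
    non_strong <- a[a$condition != "strong", ]
    fast <- nrow(non_strong) > 0L && mean(non_strong$label == 3L) > 0.5
    hybrid <- !fast && isTRUE(shares["none"] > 0.5) &&
      !isTRUE(shares["medium"] > 0.5) && !isTRUE(shares["weak"] > 0.5)
    prop_12 <- mean(a$label %in% c(1L, 2L))
    regular <- !fast && !hybrid && prop_12 > 0.5
    group <- if (fast) "Fast" else if (hybrid) "Hybrid" else
      if (regular) "Regular" else NA_character_
    data.frame(participant_id = pid, group = group, prop_12 = prop_12,
               c3_strong = shares[["strong"]], c3_medium = shares[["medium"]],
               c3_weak = shares[["weak"]], c3_none = shares[["none"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("group_assignment", class(out))
  out
}

#' Phase-portrait RMS dispersion of raw inter-tap intervals
#'
#' Embeds consecutive raw ITIs as 2-D points `(ITI_j, ITI_j+1)`, takes
#' their centroid, and computes the root-mean-square Euclidean distance of
#' the points to the centroid. Trials with dispersion strictly below the
#' threshold (default 0.1065 s) are labelled `dense`, otherwise `sparse`.
#'
#' @param itis Raw intervals in seconds, at least 3.
#' @param threshold Dense/sparse split in seconds.
#' @return List with `centroid` (length-2), `rms_dispersion` and `label`.
#' @examples
#' dispersion_metric(rep(0.3, 5))$label  # "dense": zero dispersion
#' @export
dispersion_metric <- function(itis, threshold = 0.1065) {
  itis <- as.numeric(itis)
  if (length(itis) < 3L) stop("need at least 3 intervals")
  pts <- cbind(itis[-length(itis)], itis[-1])
  centroid <- colMeans(pts)
  rms <- sqrt(mean((pts[, 1] - centroid[1])^2 + (pts[, 2] - centroid[2])^2))
  list(centroid = centroid, rms_dispersion = rms,
       label = if (rms < threshold) "dense" else "sparse")
}

#' Factorial regression of mean raw ITI on coherence, tempo and group
#'
#' Ordinary least squares of per-trial mean raw ITI on stimulus phase
#' coherence, base tempo and participant group with all interactions
#' (`mean_iti ~ r * tempo * group`), treatment coding with the Regular
#' group as reference level.
#'
#' @param data Data frame with columns `mean_iti` (seconds), `r`
#'   (stimulus coherence), `tempo` (BPM) and `group` (character/factor
#'   with levels among Regular, Hybrid, Fast).
#' @return List with `model` (the `lm` fit), `coefficients` (matrix of
#'   estimates and p-values), `r_squared` and `f_statistic`.
#' @export
fit_iti_regression <- function(data) {
  needed <- c("mean_iti", "r", "tempo", "group")
  if (!all(needed %in% names(data)))
    stop("`data` needs columns ", paste(needed, collapse = ", "))
  data$group <- factor(data$group,
                       levels = intersect(c("Regular", "Hybrid", "Fast"),
                                          unique(as.character(data$group))))
  if (nlevels(data$group) < 2L)
    stop("need at least 2 participant groups")
  form <- mean_iti ~ r * tempo * group
  if (length(unique(data$tempo)) < 2L) {
    warning("tempo is constant; tempo terms dropped from the model")
    form <- mean_iti ~ r * group
  }
  fit <- stats::lm(form, data = data)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design: aliased terms ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  sm <- summary(fit)
  list(model = fit,
       coefficients = sm$coefficients,
       r_squared = sm$r.squared,
       f_statistic = unname(sm$fstatistic))
}
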