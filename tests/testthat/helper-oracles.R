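# Independent brute-force oracles used to cross-check the package's
# implementations. These are deliberately naive (explicit loops, textbook
# formulas) and share no code with the package internals.

# ---- feature oracle -------------------------------------------------------

naive_quantile <- function(v, p) {
  # linear interpolation of order statistics (type-7 convention), by hand
  v <- sort(v)
  n <- length(v)
  if (n == 1) return(v)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

naive_summary <- function(values, mask) {
  v <- values[mask & !is.na(values)]
  if (length(v) == 0) {
    return(c(mean = NA, sd = NA, min = NA, max = NA, q1 = NA, median = NA,
             q3 = NA))
  }
  m <- sum(v) / length(v)
  s <- if (length(v) >= 2) sqrt(sum((v - m)^2) / (length(v) - 1)) else NA_real_
  c(mean = m, sd = s, min = min(v), max = max(v),
    q1 = naive_quantile(v, 0.25), median = naive_quantile(v, 0.5),
    q3 = naive_quantile(v, 0.75))
}

naive_zero_crossings <- function(values, signed, mask, tol = 0) {
  count <- 0
  for (i in seq_along(values)) {
    if (mask[i] && !is.na(values[i]) && abs(values[i]) <= tol) count <- count + 1
  }
  if (signed) {
    for (i in seq_len(length(values) - 1)) {
      a <- values[i]; b <- values[i + 1]
      if (mask[i] && mask[i + 1] && !is.na(a) && !is.na(b) &&
          abs(a) > tol && abs(b) > tol && sign(a) != sign(b)) {
        count <- count + 1
      }
    }
  }
  count
}

# Full feature vector by explicit loops over the segment samples.
naive_segment_features <- function(segment, fps = 50, tol = 0) {
  x <- segment$x_mm; y <- segment$y_mm; real <- segment$real_flag
  n <- length(x)
  vx <- vy <- speed <- numeric(n - 1)
  vvalid <- logical(n - 1)
  for (t in seq_len(n - 1)) {
    vx[t] <- (x[t + 1] - x[t]) * fps
    vy[t] <- (y[t + 1] - y[t]) * fps
    speed[t] <- sqrt(vx[t]^2 + vy[t]^2)
    vvalid[t] <- real[t] && real[t + 1]
  }
  theta <- atan2(vy, vx)
  ang <- accel <- curv <- numeric(n - 2)
  avalid <- cvalid <- logical(n - 2)
  for (t in seq_len(n - 2)) {
    d <- theta[t + 1] - theta[t]
    while (d > pi) d <- d - 2 * pi
    while (d <= -pi) d <- d + 2 * pi
    ang[t] <- abs(d)
    accel[t] <- sqrt((vx[t + 1] - vx[t])^2 + (vy[t + 1] - vy[t])^2) * fps
    step <- speed[t] / fps
    curv[t] <- if (step > 0) ang[t] / step else NA_real_
    avalid[t] <- real[t] && real[t + 1] && real[t + 2]
    cvalid[t] <- avalid[t] && step > 0
  }
  out <- c()
  sets <- list(vx = list(vx, vvalid), vy = list(vy, vvalid),
               speed = list(speed, vvalid), accel = list(accel, avalid),
               angle_change = list(ang, avalid), curvature = list(curv, cvalid))
  for (nm in names(sets)) {
    sm <- naive_summary(sets[[nm]][[1]], sets[[nm]][[2]])
    names(sm) <- paste(nm, names(sm), sep = "_")
    out <- c(out, sm)
  }
  out["vx_zero_crossings"] <- naive_zero_crossings(vx, TRUE, vvalid, tol)
  out["vy_zero_crossings"] <- naive_zero_crossings(vy, TRUE, vvalid, tol)
  out["angle_change_zero_crossings"] <-
    naive_zero_crossings(ang, FALSE, avalid, tol)
  path <- 0
  for (t in seq_len(n - 1)) if (vvalid[t]) path <- path + speed[t] / fps
  rp <- which(real)
  net <- if (length(rp) >= 2) {
    sqrt((x[rp[length(rp)]] - x[rp[1]])^2 + (y[rp[length(rp)]] - y[rp[1]])^2)
  } else NA_real_
  out["path_length"] <- path
  out["net_displacement"] <- net
  out["straightness"] <- if (is.na(net) || path == 0) 0 else min(1, net / path)
  out
}

# ---- metric oracle --------------------------------------------------------

naive_metrics <- function(calls, scores, truth) {
  pos <- function(cls) {
    tp <- sum(calls == cls & truth == cls)
    fp <- sum(calls == cls & truth != cls)
    fn <- sum(calls != cls & truth == cls)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(precision = p, recall = r, f1 = f)
  }
  ol <- pos("OL"); ut <- pos("UT")
  # ROC AUC by pairwise comparisons, ties counting one half
  auc_pairs <- function(s, is_pos) {
    num <- 0; den <- 0
    for (i in which(is_pos)) for (j in which(!is_pos)) {
      den <- den + 1
      if (s[i] > s[j]) num <- num + 1 else if (s[i] == s[j]) num <- num + 0.5
    }
    if (den == 0) NA_real_ else num / den
  }
  # average precision by explicit threshold loop over distinct scores
  ap <- function(s, is_pos) {
    if (!any(is_pos) || all(is_pos)) return(NA_real_)
    th <- sort(unique(s), decreasing = TRUE)
    prev_r <- 0; total <- 0
    for (t in th) {
      sel <- s >= t
      p <- sum(sel & is_pos) / sum(sel)
      r <- sum(sel & is_pos) / sum(is_pos)
      total <- total + (r - prev_r) * p
      prev_r <- r
    }
    total
  }
  tp <- sum(calls == "OL" & truth == "OL"); tn <- sum(calls == "UT" & truth == "UT")
  fp <- sum(calls == "OL" & truth == "UT"); fn <- sum(calls == "UT" & truth == "OL")
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  po <- (tp + tn) / length(truth)
  pe <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / length(truth)^2
  kappa <- if (pe == 1) 0 else (po - pe) / (1 - pe)
  pcl <- pmin(pmax(scores, 1e-15), 1 - 1e-15)
  y <- as.numeric(truth == "OL")
  ll <- -mean(y * log(pcl) + (1 - y) * log(1 - pcl))
  c(balanced_accuracy = (ol[["recall"]] + ut[["recall"]]) / 2,
    roc_auc = auc_pairs(scores, truth == "OL"),
    mcc = mcc, log_loss = ll, cohen_kappa = kappa,
    f1_ol = ol[["f1"]], f1_ut = ut[["f1"]],
    precision_ol = ol[["precision"]], precision_ut = ut[["precision"]],
    recall_ol = ol[["recall"]], recall_ut = ut[["recall"]],
    pr_auc_ol = ap(scores, truth == "OL"),
    pr_auc_ut = ap(1 - scores, truth == "UT"))
}

# ---- Mann-Whitney oracle --------------------------------------------------

# Exact two-sided p by enumerating which observed values go to group a.
naive_mw_exact <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a); m <- length(b)
  u_of <- function(av, bv) {
    u <- 0
    for (x in av) for (y in bv) {
      if (x > y) u <- u + 1 else if (x == y) u <- u + 0.5
    }
    u
  }
  u_obs <- u_of(a, b)
  combos <- utils::combn(n + m, n)
  centre <- n * m / 2
  extreme <- 0
  for (k in seq_len(ncol(combos))) {
    av <- pooled[combos[, k]]
    bv <- pooled[-combos[, k]]
    if (abs(u_of(av, bv) - centre) >= abs(u_obs - centre) - 1e-9) {
      extreme <- extreme + 1
    }
  }
  list(U = u_obs, p = extreme / ncol(combos))
}

# ---- decision-boundary oracle --------------------------------------------

naive_mcc <- function(pred_pos, truth_pos) {
  tp <- sum(pred_pos & truth_pos); tn <- sum(!pred_pos & !truth_pos)
  fp <- sum(pred_pos & !truth_pos); fn <- sum(!pred_pos & truth_pos)
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (denom == 0) 0 else (tp * tn - fp * fn) / denom
}

naive_boundary_sweep <- function(probs, labels) {
  truth <- labels == "OL"
  best_tau <- NA; best <- -Inf
  for (tau in seq(0.01, 0.99, by = 0.01)) {
    m <- naive_mcc(probs >= tau, truth)
    if (m > best + 1e-15) {
      best <- m; best_tau <- tau
    }
  }
  best_tau
}

# ---- Shapley oracle -------------------------------------------------------

# Parse an xgboost booster into plain-list trees usable by brute_shap().
parse_booster_trees <- function(booster) {
  dt <- xgboost::xgb.model.dt.tree(model = booster)
  df <- as.data.frame(dt)
  lapply(split(df, df$Tree), function(tr) {
    rownames(tr) <- tr$ID
    tr
  })
}

# Round to float32, the precision xgboost uses for split comparisons.
as_float32 <- function(v) {
  readBin(writeBin(as.numeric(v), raw(), size = 4), "numeric", size = 4,
          n = length(v))
}

# Cover-weighted conditional expectation of one tree given the feature
# subset S (features outside S marginalised by cover proportions).
tree_expvalue <- function(tree, x, in_S, node_id = NULL) {
  if (is.null(node_id)) node_id <- tree$ID[tree$Node == 0][1]
  node <- tree[node_id, ]
  if (node$Feature == "Leaf") return(node$Gain)
  f <- node$Feature
  yes <- node$Yes; no <- node$No
  if (in_S[[f]]) {
    go <- if (is.na(x[[f]])) node$Missing
      else if (as_float32(x[[f]]) < as_float32(node$Split)) yes else no
    return(tree_expvalue(tree, x, in_S, go))
  }
  wy <- tree[yes, "Cover"]; wn <- tree[no, "Cover"]
  (wy * tree_expvalue(tree, x, in_S, yes) +
      wn * tree_expvalue(tree, x, in_S, no)) / (wy + wn)
}

# Exact Shapley values by enumerating all 2^d coalitions.
brute_shap <- function(trees, x, feature_names) {
  d <- length(feature_names)
  v <- function(S) {
    in_S <- stats::setNames(as.list(feature_names %in% S), feature_names)
    sum(vapply(trees, tree_expvalue, numeric(1), x = x, in_S = in_S))
  }
  phi <- stats::setNames(numeric(d), feature_names)
  subsets <- lapply(0:(2^(d - 1) - 1), function(code) code)
  for (i in seq_len(d)) {
    others <- feature_names[-i]
    for (code in 0:(2^(d - 1) - 1)) {
      S <- others[bitwAnd(code, 2^(seq_len(d - 1) - 1)) > 0]
      s <- length(S)
      w <- factorial(s) * factorial(d - s - 1) / factorial(d)
      phi[i] <- phi[i] + w * (v(c(S, feature_names[i])) - v(S))
    }
  }
  phi
}
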