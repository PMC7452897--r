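# Independent brute-force oracles. These recompute quantities from first
# principles (pair enumeration, direct counting) and stay independent of the
# package's implementation paths.

# product-limit estimator by direct risk-set counting
oracle_km <- function(time, event, at) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  for (tt in ts[ts <= at]) {
    n_risk <- sum(time >= tt)
    d <- sum(time == tt & event == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}

# two-group log-rank statistic by observed-minus-expected accumulation
oracle_logrank <- function(t1, e1, t2, e2) {
  time <- c(t1, t2); event <- c(e1, e2)
  grp <- c(rep(1, length(t1)), rep(2, length(t2)))
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (tt in ts) {
    n <- sum(time >= tt); n1 <- sum(time >= tt & grp == 1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & grp == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(statistic = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# Harrell C by exhaustive pair enumeration
oracle_cindex <- function(marker, time, event) {
  n <- length(marker); conc <- 0; usable <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (time[i] == time[j]) next
    first <- if (time[i] < time[j]) i else j
    other <- if (first == i) j else i
    if (event[first] != 1) next
    usable <- usable + 1
    if (marker[first] > marker[other]) conc <- conc + 1
    else if (marker[first] == marker[other]) conc <- conc + 0.5
  }
  conc / usable
}

# uncensored ROC AUC at a horizon by case/control pair counting
oracle_auc_uncensored <- function(marker, time, horizon) {
  case <- marker[time <= horizon]
  ctrl <- marker[time > horizon]
  num <- 0
  for (m in case) num <- num + sum(m > ctrl) + 0.5 * sum(m == ctrl)
  num / (length(case) * length(ctrl))
}

# net benefit by direct confusion-matrix counting (no censoring)
oracle_net_benefit <- function(pred_event, event_by_h, pt) {
  pos <- pred_event >= pt
  tp <- sum(pos & event_by_h == 1)
  fp <- sum(pos & event_by_h == 0)
  n <- length(pred_event)
  tp / n - fp / n * pt / (1 - pt)
}

# continuous NRI by direct up/down counting (no censoring)
oracle_nri <- function(old, new, event_by_h) {
  up <- new > old; down <- new < old
  ev <- event_by_h == 1
  (mean(up[ev]) - mean(down[ev])) + (mean(down[!ev]) - mean(up[!ev]))
}

# IDI as discrimination-slope difference (no censoring)
oracle_idi <- function(old, new, event_by_h) {
  ev <- event_by_h == 1
  (mean(new[ev]) - mean(new[!ev])) - (mean(old[ev]) - mean(old[!ev]))
}

# symmetric distance-1 GLCM of a 3D label array by direct pair enumeration
oracle_glcm <- function(labels, n_bins) {
  dims <- dim(labels)
  offs <- rbind(c(1,0,0), c(0,1,0), c(0,0,1), c(1,1,0), c(1,-1,0),
                c(1,0,1), c(1,0,-1), c(0,1,1), c(0,1,-1), c(1,1,1),
                c(1,1,-1), c(1,-1,1), c(1,-1,-1))
  mats <- list()
  for (d in seq_len(nrow(offs))) {
    M <- matrix(0, n_bins, n_bins)
    for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
      a <- labels[x, y, z]
      if (a == 0) next
      q <- c(x, y, z) + offs[d, ]
      if (any(q < 1) || any(q > dims)) next
      b <- labels[q[1], q[2], q[3]]
      if (b == 0) next
      M[a, b] <- M[a, b] + 1
      M[b, a] <- M[b, a] + 1
    }
    if (sum(M) > 0) mats[[length(mats) + 1]] <- M / sum(M)
  }
  Reduce(`+`, mats) / length(mats)
}

# run-length matrix for one direction by explicit line walking
oracle_glrlm_dir <- function(labels, n_bins, off) {
  dims <- dim(labels)
  maxr <- max(dims)
  M <- matrix(0, n_bins, maxr)
  inb <- function(p) all(p >= 1) && all(p <= dims)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    a <- labels[x, y, z]
    if (a == 0) next
    prev <- c(x, y, z) - off
    if (inb(prev) && labels[prev[1], prev[2], prev[3]] == a) next
    len <- 1; cur <- c(x, y, z) + off
    while (inb(cur) && labels[cur[1], cur[2], cur[3]] == a) {
      len <- len + 1; cur <- cur + off
    }
    M[a, len] <- M[a, len] + 1
  }
  M
}

# ICC(2,1) from explicit two-way ANOVA mean squares
oracle_icc21 <- function(x) {
  n <- nrow(x); k <- ncol(x)
  row_m <- rowMeans(x); col_m <- colMeans(x); g <- mean(x)
  msr <- k * sum((row_m - g)^2) / (n - 1)
  msc <- n * sum((col_m - g)^2) / (k - 1)
  mse <- sum((x - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + g)^2) /
    ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}
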