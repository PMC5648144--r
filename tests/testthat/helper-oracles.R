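# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive: they re-derive each quantity from its definition so
# the package implementation is checked against a different route.

# AUC by exhaustive pair counting (ties count 1/2)
bf_auc <- function(obs, scores) {
  pos <- scores[obs == 1]; neg <- scores[obs == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Kendall tau-b by exhaustive concordant/discordant counting
bf_tau_b <- function(x, y) {
  n <- length(x); nc <- 0; nd <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx == dy) nc <- nc + 1
    else nd <- nd + 1
  }
  (nc - nd) / sqrt((nc + nd + tx) * (nc + nd + ty))
}

# threshold by exhaustive candidate scan
bf_threshold <- function(obs, pred) {
  cand <- sort(unique(pred))
  ss <- sapply(cand, function(t)
    mean(pred[obs == 1] >= t) + mean(pred[obs == 0] < t))
  cand[which.max(ss)]
}

# checkerboard bin by direct floor/parity arithmetic
bf_checkerboard <- function(lon, lat, res, anchor) {
  as.integer(
    1 + (floor((lon - anchor[1]) / res) + floor((anchor[2] - lat) / res)) %% 2)
}

# exhaustive checkerboard-resolution search
bf_best_resolution <- function(lon, lat, r_min, r_max, step, anchor) {
  res <- seq(r_min, r_max, by = step)
  best <- NULL
  for (r in res) {
    b <- bf_checkerboard(lon, lat, r, anchor)
    n1 <- sum(b == 1); n2 <- sum(b == 2)
    if (n1 > 0 && n2 > 0) {
      imb <- abs(n1 - n2)
      if (is.null(best) || imb < best$imb) best <- list(r = r, imb = imb)
    }
  }
  best$r
}

# even-odd ray-casting point-in-polygon (boundary points may go either way;
# callers avoid boundary cases or use known-answer fixtures)
bf_point_in_poly <- function(px, py, vx, vy) {
  n <- length(vx); inside <- FALSE
  j <- n
  for (i in 1:n) {
    if ((vy[i] > py) != (vy[j] > py) &&
        px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
      inside <- !inside
    j <- i
  }
  inside
}

# small layer helper: matrix -> grid_layer at origin (0, nrow), cell 1
toy_layer <- function(m, name = "toy") {
  m <- as.matrix(m)
  grid_layer(m, origin_x = 0, origin_y = nrow(m), cell_size = 1, name = name)
}

# a tiny self-consistent world + species for model-level tests
toy_world <- function(nr = 40, nc = 40, seed = 1, range_c = 10, range_e = 1.5) {
  cfg <- world_config(nrow = nr, ncol = nc, cell_size = 1,
                      origin_x = 0, origin_y = nr,
                      n_climate = 3, n_edaphic = 3,
                      range_climate = range_c, range_edaphic = range_e,
                      cor_climate = 0.3, cor_edaphic = 0.3,
                      mask_hole_frac = 0, seed = seed)
  gen_environment(cfg)
}

# data matrix with an exact target correlation matrix (n rows)
exact_cor_data <- function(n, R, seed = 1) {
  p <- ncol(R)
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  X <- scale(X, center = TRUE, scale = FALSE)
  S <- cov(X)
  W <- solve(chol(S))          # whiten: cov(XW) = I
  Z <- X %*% W
  Z %*% chol(R)                # color to the target correlation
}

# balanced long table for rm_anova tests
sim_rm_table <- function(n, a = 3, b = 4, subj_sd = 1, noise_sd = 1,
                         level_sd = c(0, 0, 0), seed = 1) {
  set.seed(seed)
  d <- expand.grid(species = sprintf("s%02d", 1:n),
                   predictor = paste0("P", 1:a),
                   algorithm = paste0("A", 1:b),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sd_by_level <- 1 + level_sd[match(d$predictor, paste0("P", 1:a))]
  d$TSS <- rnorm(n)[match(d$species, sprintf("s%02d", 1:n))] * subj_sd +
    rnorm(nrow(d), sd = noise_sd * sd_by_level)
  d
}
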