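# Shared fixtures, memoized so expensive objects are built once per run.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, builder(), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# Labelled archetype shape-feature set (60 masks per class).
archetype_fixture <- function() {
  memo("archetype_set", function() generate_archetype_set(60, seed = 101))
}

svm_fixture <- function() {
  memo("svm_model", function() {
    fx <- archetype_fixture()
    train_classifier(fx$features, fx$labels, family = "svm", seed = 11)
  })
}

rf_fixture <- function() {
  memo("rf_model", function() {
    fx <- archetype_fixture()
    train_classifier(fx$features, fx$labels, family = "random_forest",
                     seed = 11)
  })
}

# Brute-force rasterization oracle for the convex hull of a pixel set:
# a candidate pixel centre is inside iff it lies in some triangle of the
# fan over the hull vertices (exact integer barycentric signs).
hull_pixel_count_oracle <- function(grid) {
  idx <- which(grid, arr.ind = TRUE)
  xs <- idx[, 2]; ys <- idx[, 1]
  h <- chull(xs, ys)
  vx <- xs[h]; vy <- ys[h]
  k <- length(h)
  if (k <= 2L) return(length(xs))
  in_tri <- function(px, py, ax, ay, bx, by, cx, cy) {
    d1 <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
    d2 <- (cx - bx) * (py - by) - (cy - by) * (px - bx)
    d3 <- (ax - cx) * (py - cy) - (ay - cy) * (px - cx)
    (d1 >= 0 & d2 >= 0 & d3 >= 0) | (d1 <= 0 & d2 <= 0 & d3 <= 0)
  }
  count <- 0L
  for (px in seq(min(xs), max(xs))) {
    for (py in seq(min(ys), max(ys))) {
      inside <- FALSE
      for (t in 2:(k - 1)) {
        if (in_tri(px, py, vx[1], vy[1], vx[t], vy[t], vx[t + 1], vy[t + 1])) {
          inside <- TRUE
          break
        }
      }
      if (inside) count <- count + 1L
    }
  }
  count
}

# Rotate a mask grid by 90 degrees clockwise.
rot90_mask <- function(mask) {
  g <- mask$grid
  binary_mask(t(g)[ncol(g):1, , drop = FALSE], mask$pixel_size)
}

# A 2-state generator over BB (amoeboidal) and FP (mesenchymal), handy for
# analytic occupancy checks: pi_BB = r(FP->BB) / (r(BB->FP) + r(FP->BB)).
two_state_Q <- function(r_bf = 0.5, r_fb = 0.25) {
  rate_matrix(matrix(c(0, r_bf, r_fb, 0), 2, 2, byrow = TRUE,
                     dimnames = list(c("BB", "FP"), c("BB", "FP"))))
}

# Uniform-step model (all categories alike) for controlled step tests.
uniform_step_model <- function(mu = 0.4, s2 = 0.5) {
  cats <- step_categories()
  step_model(setNames(rep(mu, 9), cats), setNames(rep(s2, 9), cats))
}
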