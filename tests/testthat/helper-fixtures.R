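# shared fixture builders and independent oracles

# linear isotherm pi = slope * (a0 - A) sampled on [a_min, a_max], clipped at 0
make_linear_curve <- function(slope = 1, a0 = 100, a_min = 40, a_max = 100,
                              n = 200) {
  A <- seq(a_max, a_min, length.out = n)
  isotherm_curve(A, pmax(slope * (a0 - A), 0))
}

# polynomial compression isotherm with a closed-form derivative:
# pi(A) = b1*x + b2*x^2 + b3*x^3 with x = a_max - A (all b >= 0)
make_poly_curve <- function(b, a_max = 120, a_min = 45, n = 300) {
  A <- seq(a_max, a_min, length.out = n)
  x <- a_max - A
  list(curve = isotherm_curve(A, b[1] * x + b[2] * x^2 + b[3] * x^3),
       dpi_dA = function(A) -(b[1] + 2 * b[2] * (a_max - A) +
                                3 * b[3] * (a_max - A)^2))
}

# step-type curve: pi exactly 0 above area `edge`, linear rise below
make_step_curve <- function(edge = 120, a_max = 150, a_min = 60, n = 300,
                            slope = 0.8, noise = 0, seed = NULL) {
  A <- seq(a_max, a_min, length.out = n)
  p <- pmax(slope * (edge - A), 0)
  if (noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    p <- p + rnorm(n, 0, noise)
    p <- pmax(p, -0.9)
  }
  isotherm_curve(A, p)
}

# hand-built compressibility profile (for transition-detection oracles)
make_profile <- function(pressure, cs) {
  structure(list(pressure_grid = pressure,
                 area_grid = seq_along(pressure),
                 cs_inverse = cs,
                 max_cs_inverse = max(cs),
                 max_location_pressure = pressure[which.max(cs)]),
            class = "compressibility_profile")
}

# brute-force scan for prominent local minima, independent of the package's
# detector: checks every interior point against all enclosing maxima
brute_force_minima <- function(pressure, cs, prominence, exclude = 2L) {
  n <- length(cs)
  hits <- data.frame(pressure = numeric(0), depth = numeric(0))
  for (i in (exclude + 1L):(n - exclude)) {
    if (!(cs[i] <= cs[i - 1L] && cs[i] < cs[i + 1L])) next
    jl <- which(cs[1:i] < cs[i]); jl <- if (length(jl)) max(jl) else 1L
    jr <- which(cs[i:n] < cs[i]); jr <- if (length(jr)) i + min(jr) - 1L else n
    depth <- min(max(cs[jl:i]), max(cs[i:jr])) - cs[i]
    if (depth >= prominence)
      hits <- rbind(hits, data.frame(pressure = pressure[i], depth = depth))
  }
  hits
}

# exact Pn3m reflection positions for lattice parameter a (nm -> nm^-1)
pn3m_positions <- function(a, N = c(2, 3, 4, 6, 8, 9)) 2 * pi * sqrt(N) / a
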