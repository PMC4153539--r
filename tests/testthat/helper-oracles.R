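# Closed-form oracles derived independently of the package's root searches.
# With survival s = 1 - d and rho = s * r:
#   MSS     f = s r / (1 + (r-1) x^b)        =>  x_hat = ((rho-1)/(r-1))^(1/b)
#   Ricker  f = s exp(r (1 - x^b))           =>  x_hat^b = 1 + log(s)/r
#   Hassell f = s r / (1 + (r^(1/b)-1) x)^b  =>  x_hat = (rho^(1/b)-1)/(r^(1/b)-1)
# and the slope of N f(N) at equilibrium (complexity) linearizes to
#   MSS     c = 1 - b (rho - 1)/rho
#   Ricker  c = 1 - b (r + log(s))
#   Hassell c = 1 - b (1 - rho^(-1/b))

mss_nhat_closed <- function(r, K, b, d) {
  K * (((1 - d) * r - 1) / (r - 1))^(1 / b)
}

mss_bcri_closed <- function(r, d) {
  rho <- (1 - d) * r
  2 * rho / (rho - 1)
}

ricker_bcri_closed <- function(r, d) 2 / (r + log(1 - d))

# central finite-difference slope of N f(N), the numeric complexity oracle
fd_complexity <- function(params, mod = NULL, rel_step = 1e-6) {
  Nhat <- equilibrium_density(params, mod)
  h <- rel_step * Nhat
  g <- function(N) N * reproduction_ratio(params, N, mod)
  (g(Nhat + h) - g(Nhat - h)) / (2 * h)
}

mss_base <- function(K = 100) growth_params("mss", r = 5, K = K, b = 1,
                                            d = 0.05)

model_presets <- list(
  mss = list(model = "mss", r = 5),
  hassell = list(model = "hassell", r = 40),
  ricker = list(model = "ricker", r = 0.5))
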