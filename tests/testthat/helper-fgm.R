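# shared fixtures for the suite; everything is generated in code

# inverse thermal energy at 300 K, used in hand-computed expectations
BETA300 <- 1 / (1.987204e-3 * 300)
RT300 <- 1.987204e-3 * 300

# a standard normal work spec and a strongly separated mixture at 300 K
spec_normal <- function() mixture_spec(1, 0, 1, 300)
spec_separated <- function() mixture_spec(c(0.7, 0.3), c(0, 4), c(0.3, 0.3), 300)
spec_narrow_qq <- function() mixture_spec(1, 1, 0.2, 300)

# mild mixture whose totals land in the Anderson-Darling gray zone at
# documented seeds (see test-estimators.R), with its recharging-stage spec
spec_grayzone <- function() mixture_spec(c(0.8, 0.2), c(0, 2), c(1, 1), 300)
spec_gray_qq <- function() mixture_spec(1, 0.5, 0.3, 300)

random_work_set <- function(n = 20, temperature = 300) {
  work_set(stats::rnorm(n, sd = stats::runif(1, 0.2, 3)), temperature)
}

write_temp_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
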