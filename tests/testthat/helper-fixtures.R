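# build a one-week window from per-slot glucose vectors
make_week <- function(pre = numeric(), din = numeric()) {
  data.frame(
    slot = c(rep("prebreakfast", length(pre)), rep("predinner", length(din))),
    glucose = c(pre, din)
  )
}

# random review window: 0-7 readings per slot drawn from a grid spanning
# hypoglycemic, in-band and hyperglycemic values
rand_window <- function() {
  grid <- c(2.2, 2.8, 3.1, 3.5, 3.9, 4.5, 6.0, 7.9, 8.4, 9.5, 10.5, 12.0, 15.0)
  make_week(
    pre = sample(grid, sample(0:7, 1), replace = TRUE),
    din = sample(grid, sample(0:7, 1), replace = TRUE)
  )
}

# random regimen with whole-unit doses
rand_regimen <- function() {
  regimen(sample(0:80, 1), sample(0:80, 1), runif(1, 45, 120))
}

default_cfg <- titrationConfig()
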