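# shared fixtures: the benchmark rate sets and the four reference initial
# conditions with their closed-form predictions
main_rates <- rate_set(1, 1/4, 1/16)
s2_rates <- rate_set(1, 1/16, 1/4)

table2_ics <- list(
  square   = c(0.00, 1.00, 0.00),
  triangle = c(0.25, 0.75, 0.00),
  diamond  = c(0.50, 0.25, 0.25),
  nabla    = c(0.75, 0.00, 0.00)
)
table2_m <- c(square = 0.80, triangle = 0.65, diamond = 0.55, nabla = 0.15)
table2_Tcons <- c(square = 2563.0, triangle = 3316.2,
                  diamond = 3524.6, nabla = 2165.1)

# red/blue colour swap of an initial condition triple
swap_ic <- function(ic) c(ic[2L], ic[1L], 1 - sum(ic))

ci_covers <- function(ci, value) {
  ci[["conf.low"]] <= value && value <= ci[["conf.high"]]
}

intervals_overlap <- function(lo1, hi1, lo2, hi2) {
  lo1 <= hi2 && lo2 <= hi1
}
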