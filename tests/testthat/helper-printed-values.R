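# Published reference values the replication targets.
# Rates are percentages; rows ordered by descending charge rate r.

t1_r <- c(1.00, 0.75, 0.50, 0.35, 0.25, 0.15, 0.05)
t1_mu <- c(0.0287, 0.0376, 0.0567, 0.0800, 0.1123, 0.1808, 0.4841)
t1_years <- c(5, 10, 15, 20, 25)
t1_rates <- matrix(c(
  10.2, 14.7, 16.8, 17.8, 18.3,
  12.9, 18.4, 21.0, 22.2, 22.8,
  18.1, 25.1, 28.4, 30.0, 30.9,
  24.0, 32.6, 36.3, 38.2, 39.1,
  30.9, 40.7, 44.7, 46.7, 47.6,
  41.9, 52.5, 56.7, 58.7, 59.6,
  65.9, 74.9, 77.9, 79.3, 80.0
), nrow = 7, byrow = TRUE,
  dimnames = list(paste0("r", t1_r), paste0("y", t1_years)))

# 5-year panel of the desistance sensitivity grid; rows d, columns r.
t2_d <- c(0.20, 0.123, 0.05, 0)
t2_5y <- matrix(c(
  13.2, 16.9, 23.0, 30.7, 37.5, 48.7, 71.4,
  10.2, 12.9, 18.1, 24.0, 30.9, 41.9, 65.9,
   6.5,  8.5, 12.4, 17.2, 21.8, 31.5, 57.7,
   4.3,  5.6,  8.3, 11.3, 15.2, 23.4, 47.7
), nrow = 4, byrow = TRUE,
  dimnames = list(paste0("d", t2_d), paste0("r", t1_r)))

# 25-year values quoted in the sensitivity analysis text.
t2_25y_text <- data.frame(
  d = c(0.20, 0, 0.20, 0),
  r = c(1, 1, 0.05, 0.05),
  rate = c(18.5, 18.6, 78.9, 82.1)
)

# Extract the Monte Carlo rate matrix (percent) from a replicate_table1()
# result, ordered to match t1_rates.
table1_pct <- function(t1, method = "monte_carlo") {
  m <- t1[t1$method == method, ]
  m <- m[order(-m$r), ]
  100 * as.matrix(m[, paste0("y", t1_years)])
}

# Extract the 5-year panel (percent) from a replicate_table2() result.
table2_5y_pct <- function(t2, method = "monte_carlo") {
  g <- t2[t2$horizon == 5 & t2$method == method, ]
  g <- g[order(match(g$d, t2_d), -g$r), ]
  matrix(100 * g$rate, nrow = length(t2_d), byrow = TRUE,
         dimnames = dimnames(t2_5y))
}
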