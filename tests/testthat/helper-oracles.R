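# Independent brute-force oracles and small fixture builders. These are
# deliberately written as naive per-element loops, independent of the
# vectorized / compiled implementations they check.

# Mean amplitude deviation of the resultant, double loop, in mg.
oracle_mad <- function(block) {
  n <- nrow(block)
  r <- numeric(n)
  for (i in seq_len(n)) r[i] <- sqrt(block[i, 1]^2 + block[i, 2]^2 + block[i, 3]^2)
  rave <- sum(r) / n
  s <- 0
  for (i in seq_len(n)) s <- s + abs(r[i] - rave)
  1000 * s / n
}

# Sum of axis-wise mean absolute deviations, in mg.
oracle_madxyz <- function(block) {
  n <- nrow(block)
  total <- 0
  for (k in 1:3) {
    ave <- sum(block[, k]) / n
    for (i in seq_len(n)) total <- total + abs(block[i, k] - ave)
  }
  1000 * total / n
}

# Naive per-sample simulation of the trigger state machine. Mirrors the
# documented behavior sample by sample with explicit state labels.
oracle_trigger <- function(a, rate, arm_mg = 187.5, confirm_mg = 500,
                           window_s = 5, quiet_s = 5) {
  n <- nrow(a)
  active <- rep(FALSE, n)
  if (n == 0) return(active)
  arm <- arm_mg / 1000
  confirm <- confirm_mg / 1000
  window <- round(window_s * rate)
  quiet <- round(quiet_s * rate)
  ref <- a[1, ]
  state <- "quiescent"
  arm_i <- NA_integer_
  last_ex <- NA_integer_
  for (i in seq_len(n)) {
    dev <- max(abs(a[i, ] - ref))
    if (state == "armed" && (i - arm_i) > window) state <- "quiescent"
    if (state == "quiescent") {
      if (dev > arm) {
        state <- "armed"
        arm_i <- i
        ref <- a[i, ]
      }
    } else if (state == "armed") {
      if (dev > confirm) {
        state <- "active"
        active[arm_i:i] <- TRUE
        last_ex <- i
        ref <- a[i, ]
      } else if (dev > arm) {
        ref <- a[i, ]
      }
    } else {
      if (dev > arm) {
        active[(last_ex + 1):i] <- TRUE
        last_ex <- i
        ref <- a[i, ]
      } else if ((i - last_ex) > quiet) {
        state <- "quiescent"
      }
    }
  }
  active
}

# Rank-residualize-correlate partial Spearman via explicit normal equations.
oracle_partial_spearman <- function(x, y, age, sex) {
  rx <- rank(x); ry <- rank(y)
  ac <- age - mean(age)
  X <- cbind(1, ac, ac^2, as.numeric(factor(sex)) - 1)
  P <- X %*% solve(t(X) %*% X) %*% t(X)
  ex <- rx - P %*% rx
  ey <- ry - P %*% ry
  sum((ex - mean(ex)) * (ey - mean(ey))) /
    sqrt(sum((ex - mean(ex))^2) * sum((ey - mean(ey))^2))
}

# Fixture builders ------------------------------------------------------------

const_recording <- function(minutes, g = c(0, 0, 1), rate = 10,
                            start = as.POSIXct("2024-03-04 08:00:00", tz = "UTC")) {
  n <- round(minutes * 60 * rate)
  raw_recording(matrix(rep(g, each = n), n, 3), sampling_rate = rate,
                start_time = start)
}

# A synthetic epoch table with the given per-epoch fields, defaulting the
# bookkeeping columns; used by the summary-level tests.
make_epochs <- function(n, start = as.POSIXct("2024-03-04 00:00:00", tz = "UTC"),
                        mad_mg = 10, madxyz_mg = 15, steps = 0L,
                        wear = TRUE, ape_deg = NA_real_, is_reference = FALSE,
                        epoch_s = 6) {
  df <- data.frame(start_time = start + (seq_len(n) - 1) * epoch_s,
                   n_samples = rep_len(600L, n),
                   mad_mg = rep_len(mad_mg, n),
                   madxyz_mg = rep_len(madxyz_mg, n),
                   xave_g = rep_len(0, n), yave_g = rep_len(0, n),
                   zave_g = rep_len(1, n), rave_g = rep_len(1, n),
                   steps = rep_len(steps, n),
                   met = rep_len(NA_real_, n), wear = rep_len(wear, n),
                   is_reference = rep_len(is_reference, n),
                   ux = rep_len(0, n), uy = rep_len(0, n), uz = rep_len(1, n),
                   stationary = rep_len(NA, n), ape_deg = rep_len(ape_deg, n))
  df$met <- estimate_met(df$mad_mg, df$madxyz_mg)
  df$stationary <- df$wear & df$mad_mg < 22.5
  df$ape_deg[!df$stationary] <- NA_real_
  df$posture <- classify_posture(df$ape_deg)
  df
}

# A one-day epoch table (14400 epochs) built from posture minutes.
make_day <- function(date = as.Date("2024-03-04"),
                     settings = 12, wear = TRUE) {
  start <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  ep <- make_epochs(14400, start = start, mad_mg = 10, wear = wear,
                    ape_deg = 20)
  if (settings > 0) {
    i <- seq_len(settings)
    ep$is_reference[i] <- TRUE
    ep$mad_mg[i] <- 250; ep$madxyz_mg[i] <- 300; ep$steps[i] <- 10L
    ep$met[i] <- estimate_met(250, 300)
    ep$stationary[i] <- FALSE
    ep$ape_deg[i] <- NA_real_
    ep$posture[i] <- NA
  }
  ep
}

# Schedule mixing walking with the four scripted postures.
mixed_schedule <- function(stationary_s = 300, noise_mg = 5) {
  activity_schedule(
    duration_s = c(60, stationary_s, 60, stationary_s, 60, stationary_s, 60,
                   stationary_s),
    activity = c("walking", "standing", "walking", "desk_sitting", "walking",
                 "sofa_sitting", "walking", "lying"),
    tilt_deg = c(0, 0, 0, 20, 0, 45, 0, 85),
    noise_mg = noise_mg)
}
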