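# Small hand-built survey fixtures used across the unit tests.

make_individuals <- function(sample_id, length_mm, sex = "juvenile",
                             ovigerous = FALSE) {
  data.frame(sample_id = sample_id, length_mm = length_mm,
             sex = rep_len(sex, length(length_mm)),
             ovigerous = rep_len(ovigerous, length(length_mm)),
             stringsAsFactors = FALSE)
}

# A two-site, two-round micro-survey with known counts.
tiny_survey <- function() {
  nets <- expand.grid(site = c("A", "B"), round = c("R1", "R2"),
                      night = c("N1", "N2"), net = 1:2,
                      stringsAsFactors = FALSE)
  nets$sample_id <- with(nets, paste(site, round, night, net, sep = "_"))
  nets$subsample_fraction <- 0.5
  nets$filtered_volume_m3 <- 10
  cores <- expand.grid(site = c("A", "B"), round = c("R1", "R2"),
                       core = 1:3, stringsAsFactors = FALSE)
  cores$sample_id <- with(cores, paste(site, round, "core", core, sep = "_"))
  cores$core_area_m2 <- 0.00385

  set.seed(99)
  net_ind <- do.call(rbind, lapply(nets$sample_id, function(id) {
    n <- 5
    make_individuals(id, round(runif(n, 1, 3.9), 2))
  }))
  core_ind <- do.call(rbind, lapply(cores$sample_id, function(id) {
    rbind(make_individuals(id, round(runif(4, 1, 3.9), 2)),
          make_individuals(id, round(runif(2, 4.1, 8), 2),
                           sex = c("male", "female")))
  }))
  survey(nets, net_ind, cores, core_ind)
}

# Balanced factorial responses for ANOVA oracle checks.
balanced_anova_data <- function(a = 2, b = 2, c = 2, n = 2, seed = 5) {
  set.seed(seed)
  d <- expand.grid(site = paste0("S", 1:a), round = paste0("R", 1:b),
                   night = paste0("N", 1:c), rep = 1:n,
                   stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d))
  d
}

# Sequential-SS linear-model oracle for the balanced crossed/nested layout.
lm_anova_oracle <- function(d) {
  d$site <- factor(d$site); d$round <- factor(d$round)
  d$nightf <- interaction(d$round, d$night, drop = TRUE)
  fit <- lm(y ~ round + site + round:site + nightf + site:nightf, data = d)
  as.data.frame(anova(fit))
}

table2_ms <- c(round = 7.282, site = 11.666, round_site = 1.112,
               night_round = 0.969, site_night_round = 0.248, error = 0.047)
table2_df <- c(round = 2, site = 8, round_site = 16, night_round = 6,
               site_night_round = 48, error = 160)
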