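# shared fixtures, all built in code

demo_tables <- function() {
  list(male = demo_weight_table("male"),
       female = demo_weight_table("female"))
}

# a tiny hand-auditable weight table: every stage advance weighs
# total/8 except where stated; used where exact sums matter
flat_weight_table <- function(sex = "male",
                              tot = c(I1 = 10, I2 = 10, C = 10, PM1 = 15,
                                      PM2 = 15, M1 = 20, M2 = 20)) {
  w <- t(vapply(tot, function(h) seq(0, h, length.out = 9), numeric(9)))
  dimnames(w) <- list(names(tot), demirjian_stages())
  stage_weight_table(sex, w, provenance = "flat test table")
}

# rating with all teeth at one stage
uniform_rating <- function(stage, sex = "male", id = "S1", ca = 8) {
  tooth_stage_rating(id, sex,
                     setNames(rep(stage, 7), demirjian_teeth()),
                     ca_years = ca)
}

random_rating <- function(id, sex = "male", ca = NULL) {
  if (is.null(ca)) ca <- runif(1, 4, 14 - 1e-9)
  tooth_stage_rating(id, sex,
                     setNames(sample(demirjian_stages(), 7, replace = TRUE),
                              demirjian_teeth()),
                     ca_years = ca)
}

# demo generating cubic whose age span covers the full cohort window
# [4, 14]: age(x) = 3.8 + 0.104 x on [0, 100], as a cubic
demo_generating_model <- function(sex = "male") {
  cubic_model(3.8, 0.104, 0, 0, sex, score_range = c(0, 100),
              name = "demo generator", provenance = "test fixture")
}

# a sample of length n with exactly the requested mean and sd
sample_with_moments <- function(n, mean, sd) {
  x <- seq_len(n)
  x <- (x - mean(x)) / stats::sd(x)
  mean + sd * x
}
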