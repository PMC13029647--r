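# Independent textbook-formula Pearson implementation used as an oracle.
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

test_that("pearson_r matches hand cases and the textbook formula", {
  expect_equal(pearson_r(c(1, 2, 3), c(6, 4, 2)), -1)
  expect_equal(pearson_r(c(0, 1, 2), c(0, 1, 0)), 0)
  x <- c(5, 12.5, 37.5); y <- c(10, 8, 1)
  expect_equal(pearson_r(x, y), pearson_oracle(x, y), tolerance = 1e-12)
  set.seed(13)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    expect_equal(pearson_r(x, y), pearson_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("pearson_r is symmetric, affine-invariant and bounded", {
  set.seed(17)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(6)
    r <- pearson_r(x, y)
    expect_equal(r, pearson_r(y, x))
    expect_equal(r, pearson_r(3 * x + 2, 0.5 * y - 7), tolerance = 1e-12)
    expect_true(r >= -1 && r <= 1)
  }
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r(1:3, 1:4), "length")
  expect_error(pearson_r(1:2, 2:3), "at least 3")
})

make_table <- function() {
  abundance_table(data.frame(
    sample_id = paste0("s", 1:4),
    day = c(11, 22, 27, 34),
    reactor = "experimental",
    pcb_gL = c(5, 11.9, 28.3, 35.5),
    GenusA = 80 - c(5, 11.9, 28.3, 35.5),   # exact negative linear response
    GenusB = c(10, 10, 10, 10),             # constant: undefined correlation
    GenusC = c(1, 3, 9, 12)))
}

test_that("correlate_genera agrees column-wise with pearson_r", {
  tab <- make_table()
  res <- correlate_genera(tab)
  expect_equal(res$r[res$genus == "GenusA"], -1)
  expect_false(res$defined[res$genus == "GenusB"])
  expect_equal(res$r[res$genus == "GenusC"],
               pearson_r(tab$pcb_gL, tab$GenusC))
  res_p <- correlate_genera(tab, p_values = TRUE)
  expect_true(all(is.na(res_p$p_value) == !res_p$defined))
})

test_that("presence mode binarises the exposure", {
  df <- data.frame(sample_id = paste0("s", 1:4), day = c(0, 11, 22, 34),
                   reactor = c("control", rep("experimental", 3)),
                   pcb_gL = c(0, 5, 11.9, 35.5),
                   GenusA = c(20, 9, 8, 2))
  tab <- abundance_table(df)
  res <- correlate_genera(tab, mode = "presence")
  expect_equal(res$r, pearson_r(c(0, 1, 1, 1), df$GenusA))
})

test_that("exposure encoding joins sample days to the dilution series", {
  ser <- run_schedule(5, pcb_feed_schedule())
  tab <- abundance_table(data.frame(
    sample_id = c("e11", "e22", "e34", "c34"),
    day = c(11, 22, 34, 34),
    reactor = c(rep("experimental", 3), "control"),
    Ferroplasma = c(10, 5, 1, 30), Leptospirillum = c(60, 65, 70, 40)))
  exposure <- encode_exposure(tab, ser)
  expect_equal(round(as.vector(exposure), 1), c(5, 11.9, 35.5, 0))
  # presence mode, and a day between steps takes the previous step's value
  pres <- encode_exposure(tab, ser, mode = "presence")
  expect_equal(as.numeric(pres), c(1, 1, 1, 0))
  tab2 <- abundance_table(data.frame(
    sample_id = "x", day = 15, reactor = "experimental",
    Ferroplasma = 10, Leptospirillum = 60))
  expect_equal(unname(encode_exposure(tab2, ser)[1]), 8)  # day-14 value
  tab3 <- abundance_table(data.frame(
    sample_id = "x", day = -2, reactor = "experimental",
    Ferroplasma = 10, Leptospirillum = 60))
  expect_error(encode_exposure(tab3, ser), "precedes")
})

test_that("abundance validation rejects bad rows with diagnostics", {
  base <- data.frame(sample_id = "s1", day = 1, reactor = "control")
  expect_error(abundance_table(cbind(base, A = 130)), "outside")
  expect_error(abundance_table(cbind(base, A = 70, B = 60)), "exceeds")
  expect_error(abundance_table(cbind(base, A = 70, Other = 10)), "Other")
  # partial table without Other is fine
  tab <- abundance_table(cbind(base, A = 60, B = 25))
  expect_equal(genera(tab), c("A", "B"))
})

test_that("programmed negative responders correlate negatively", {
  neg <- vapply(1:40, function(s) {
    b <- generate_continuous_cascade(synthetic_scenario(seed = s))
    tab <- b$abundance
    sub <- tab[tab$reactor == "experimental", ]
    sub <- abundance_table(as.data.frame(sub))
    res <- correlate_genera(sub)
    res$r[res$genus == "Ferroplasma"] < 0
  }, logical(1))
  expect_gte(mean(neg), 0.95)
})
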