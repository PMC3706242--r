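test_that("packaged parameter set is complete and valid", {
  p <- cd_parameters()
  expect_s3_class(p, "cd_params")
  expect_identical(nrow(p), 54L)
  expect_true(all(p$value >= 0))
  expect_setequal(unique(p$source),
                  c("literature", "assumed", "calculated", "fitted"))
  # the source breakdown of the full model
  expect_identical(sum(p$source == "fitted"), 31L)
  expect_identical(sum(p$source == "literature"), 17L)
  expect_identical(sum(p$source == "assumed"), 2L)
  expect_identical(sum(p$source == "calculated"), 4L)
  # intervals, where present, bracket the value
  has_ci <- !is.na(p$ci_lo)
  expect_true(all(p$ci_lo[has_ci] <= p$value[has_ci]))
  expect_true(all(p$ci_hi[has_ci] >= p$value[has_ci]))
})

test_that("parameter validation names offenders", {
  p <- cd_parameters()
  dup <- rbind(p, p[3, ])
  expect_error(validate_parameters(dup), p$name[3])
  neg <- p
  neg$value[5] <- -1
  expect_error(validate_parameters(neg), "negative")
  badci <- p
  i <- which(!is.na(badci$ci_lo))[1]
  badci$ci_lo[i] <- badci$value[i] * 2
  badci$ci_hi[i] <- badci$value[i] * 3
  expect_error(validate_parameters(badci), badci$name[i])
})

test_that("reduced tables load with a warning, not an error", {
  p <- cd_parameters()[1:10, ]
  tmp <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(p, tmp)
  expect_warning(read_parameters(tmp), "10")
})

test_that("write/read round trip preserves the table", {
  p <- cd_parameters()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_parameters(p, tmp)
  p2 <- read_parameters(tmp)
  expect_equal(as.data.frame(p2), as.data.frame(p), tolerance = 1e-12)
})

test_that("param_update modifies exactly the named values", {
  p <- cd_parameters()
  p2 <- param_update(p, ksab = 99, TG2_level = 0)
  expect_identical(param_value(p2, "ksab"), 99)
  expect_identical(param_value(p2, "TG2_level"), 0)
  untouched <- setdiff(p$name, c("ksab", "TG2_level"))
  expect_identical(p2$value[match(untouched, p2$name)],
                   p$value[match(untouched, p$name)])
  expect_error(param_update(p, not_a_parameter = 1), "not_a_parameter")
})
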