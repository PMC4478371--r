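# Scenario loading, validation, serialization, result CSVs.

test_that("the bundled scenario loads with the three melanoma strategies", {
  sc <- load_scenario(fixture_path())
  expect_s3_class(sc, "cea_scenario")
  expect_equal(names(sc$strategies), c("dacarbazine", "dabrafenib", "vemurafenib"))
  expect_equal(sc$strategies$dabrafenib$monthly_drug_cost$base, 7569.60)
  expect_equal(sc$wtp_default, 1e5)
})

test_that("the bundled scenario carries every published economic cell", {
  sc <- load_scenario(fixture_path())
  g <- function(strategy, field) sc$strategies[[strategy]][[field]]
  ae <- function(strategy, name, band) {
    s <- sc$strategies[[strategy]]
    key <- vapply(s$adverse_events, function(a) paste(a$name, a$grade_band), character(1))
    s$adverse_events[[match(paste(name, band), key)]]
  }

  # monthly drug costs with their sensitivity ranges (2013 USD, gamma)
  for (row in list(
    list("dacarbazine", 988.86, 678.29, 1356.85),
    list("dabrafenib", 7569.60, 5677.20, 9462.00),
    list("vemurafenib", 10807.40, 8105.55, 13509.25))) {
    d <- g(row[[1]], "monthly_drug_cost")
    expect_equal(c(d$base, d$low, d$high), c(row[[2]], row[[3]], row[[4]]))
    expect_equal(d$family, "gamma")
  }

  # composite utilities (beta, printed range 0-1)
  utils_tab <- list(
    dacarbazine = c(0.69, 0.45), dabrafenib = c(0.79, 0.52),
    vemurafenib = c(0.73, 0.49))
  for (nm in names(utils_tab)) {
    expect_equal(g(nm, "utility_stable")$base, utils_tab[[nm]][1])
    expect_equal(g(nm, "utility_progression")$base, utils_tab[[nm]][2])
    expect_equal(g(nm, "utility_stable")$family, "beta")
    expect_equal(c(g(nm, "utility_stable")$low, g(nm, "utility_stable")$high), c(0, 1))
  }

  # crossover rule: chemotherapy arm pays the dabrafenib price in progression
  expect_equal(g("dacarbazine", "crossover_monthly_cost"), 7569.60)
  expect_equal(g("dabrafenib", "crossover_monthly_cost"), 0)
  expect_equal(g("vemurafenib", "crossover_monthly_cost"), 0)

  # adverse-event probabilities (per strategy, nonzero rows only)
  probs <- list(
    dacarbazine = list(c("vomiting_nausea", "g12", 0.0106),
                       c("vomiting_nausea", "g34", 0.0007),
                       c("diarrhea", "g12", 0.0006),
                       c("diarrhea", "g34", 0.0001),
                       c("neutropenia", "g12", 0.0019),
                       c("neutropenia", "g34", 0.0086),
                       c("leukopenia", "g12", 0.0013),
                       c("leukopenia", "g34", 0.0007),
                       c("thrombocytopenia", "g34", 0.0020)),
    dabrafenib = list(c("vomiting_nausea", "g12", 0.0009),
                      c("hyperkeratosis", "g12", 0.0113),
                      c("hyperkeratosis", "g34", 0.0009),
                      c("squamous_cell_carcinoma", "g12", 0.0018),
                      c("squamous_cell_carcinoma", "g34", 0.0036),
                      c("neutropenia", "g34", 0.0004),
                      c("ppe", "g12", 0.0055),
                      c("ppe", "g34", 0.0018)),
    vemurafenib = list(c("vomiting_nausea", "g12", 0.0023),
                       c("vomiting_nausea", "g34", 0.0010),
                       c("diarrhea", "g12", 0.0230),
                       c("diarrhea", "g34", 0.0005),
                       c("hyperkeratosis", "g12", 0.0172),
                       c("hyperkeratosis", "g34", 0.0010),
                       c("skin_papilloma", "g12", 0.0169),
                       c("squamous_cell_carcinoma", "g34", 0.0105),
                       c("keratoacanthoma", "g12", 0.0051),
                       c("neutropenia", "g12", 0.0002),
                       c("neutropenia", "g34", 0.0002)))
  for (nm in names(probs)) {
    expect_length(sc$strategies[[nm]]$adverse_events, length(probs[[nm]]))
    for (row in probs[[nm]]) {
      a <- ae(nm, row[1], row[2])
      expect_false(is.null(a), info = paste(nm, row[1], row[2]))
      expect_equal(a$monthly_probability$base, as.numeric(row[3]),
                   info = paste(nm, row[1], row[2]))
    }
  }

  # toxicity management costs (USD per month on treatment, gamma)
  costs <- list(
    c("vemurafenib", "hyperkeratosis", "g12", 126.66, 114.26, 424.95),
    c("vemurafenib", "hyperkeratosis", "g34", 1082.84, 1070.84, 1706.93),
    c("vemurafenib", "squamous_cell_carcinoma", "g34", 1595, 1128, 3408),
    c("vemurafenib", "vomiting_nausea", "g12", 274.58, 274.58, 419.54),
    c("vemurafenib", "vomiting_nausea", "g34", 6855.76, 4480.05, 8009.39),
    c("vemurafenib", "diarrhea", "g12", 5.81, 5.81, 45.89),
    c("vemurafenib", "diarrhea", "g34", 7404.11, 3550.28, 7845),
    c("vemurafenib", "keratoacanthoma", "g12", 113.67, 66.72, 181.31),
    c("vemurafenib", "skin_papilloma", "g12", 73, 61, 97),
    c("dabrafenib", "ppe", "g12", 113.67, 113.67, 178.62),
    c("dabrafenib", "squamous_cell_carcinoma", "g12", 1595, 1128, 3408),
    c("dacarbazine", "vomiting_nausea", "g12", 84.66, 2.78, 4485.98),
    c("dacarbazine", "vomiting_nausea", "g34", 6665.84, 4208.25, 12075.84))
  for (row in costs) {
    a <- ae(row[1], row[2], row[3])
    expect_equal(c(a$management_cost$base, a$management_cost$low, a$management_cost$high),
                 as.numeric(row[4:6]), info = paste(row[1:3], collapse = " "))
  }
})

test_that("schema violations are rejected with field paths", {
  sc <- melanoma_scenario()

  bad_util <- sc
  bad_util$strategies$dabrafenib$utility_stable <- dist_spec(0.79)
  bad_util$strategies$dabrafenib$utility_stable$base <- 1.2 # bypass constructor
  path <- scenario_tempfile(bad_util)
  expect_error(load_scenario(path), "utility_stable",
               class = "melcea_validation_error")

  raw <- yaml::read_yaml(fixture_path())
  raw$no_such_key <- 1
  p2 <- tempfile(fileext = ".yaml"); yaml::write_yaml(raw, p2)
  expect_error(load_scenario(p2), "unknown key",
               class = "melcea_validation_error")

  raw2 <- yaml::read_yaml(fixture_path())
  raw2$schema_version <- 99
  p3 <- tempfile(fileext = ".yaml"); yaml::write_yaml(raw2, p3)
  expect_error(load_scenario(p3), "schema_version",
               class = "melcea_validation_error")

  raw3 <- yaml::read_yaml(fixture_path())
  raw3$strategies[[1]]$adverse_events[[1]]$monthly_probability$base <- 1.5
  p4 <- tempfile(fileext = ".yaml"); yaml::write_yaml(raw3, p4)
  expect_error(load_scenario(p4), "monthly_probability",
               class = "melcea_validation_error")

  expect_error(load_scenario(tempfile()), "not found", class = "melcea_io_error")
})

test_that("JSON round trip reproduces all numeric fields exactly", {
  sc <- melanoma_scenario()
  back <- load_scenario(scenario_tempfile(sc, ".json"))
  for (nm in names(sc$strategies)) {
    s1 <- sc$strategies[[nm]]; s2 <- back$strategies[[nm]]
    expect_identical(s1$monthly_drug_cost, s2$monthly_drug_cost)
    expect_identical(s1$utility_stable, s2$utility_stable)
    expect_identical(s1$utility_progression, s2$utility_progression)
    expect_identical(s1$crossover_monthly_cost, s2$crossover_monthly_cost)
    expect_equal(length(s1$adverse_events), length(s2$adverse_events))
    for (j in seq_along(s1$adverse_events))
      expect_identical(s1$adverse_events[[j]]$management_cost,
                       s2$adverse_events[[j]]$management_cost)
    expect_identical(sc$survival[[nm]]$os$survival, back$survival[[nm]]$os$survival)
    expect_identical(sc$survival[[nm]]$pfs$survival, back$survival[[nm]]$pfs$survival)
  }
  expect_identical(sc$wtp_default, back$wtp_default)

  # YAML round trip at 15 significant digits preserves the fixture too
  back_y <- load_scenario(scenario_tempfile(sc, ".yaml"))
  expect_equal(back_y$strategies$dacarbazine$monthly_drug_cost$base, 988.86)
  expect_equal(back_y$survival$dabrafenib$os$survival,
               sc$survival$dabrafenib$os$survival, tolerance = 1e-14)
})

test_that("frontier CSV has the documented columns and round-trips", {
  fr <- build_frontier(data.frame(
    name = c("dacarbazine", "dabrafenib", "vemurafenib"),
    total_cost = c(15221.456, 38547.123, 49938.789),
    total_qaly = c(0.18204321, 0.33851234, 0.29054321)))
  path <- tempfile(fileext = ".csv")
  write_results(fr, path)
  got <- utils::read.csv(path)
  expect_equal(names(got), c("name", "total_cost", "total_qaly", "inc_cost",
                             "inc_qaly", "icer", "status"))
  expect_false(is.unsorted(got$total_cost))
  expect_equal(got$total_cost, round(fr$total_cost, 2), tolerance = 1e-9)
  expect_equal(got$total_qaly, fr$total_qaly, tolerance = 1e-4)
})

test_that("result and CEAC writers handle plain and empty inputs", {
  res <- run_scenario(two_arm_flat_scenario())
  path <- tempfile(fileext = ".csv")
  write_results(res, path)
  got <- utils::read.csv(path)
  expect_equal(nrow(got), 2)
  expect_false(is.unsorted(got$total_cost))

  empty <- data.frame(wtp = numeric(0), a = numeric(0), b = numeric(0))
  class(empty) <- c("ceac_curve", "data.frame")
  p2 <- tempfile(fileext = ".csv")
  write_results(empty, p2)
  lines <- readLines(p2)
  expect_equal(length(lines), 1L) # header only
  expect_equal(lines, "wtp,a,b")
})

test_that("survival CSV reader and {csv:} references work", {
  cv <- generate_curves(curve_generator_spec(9, 3))
  p <- tempfile(fileext = ".csv")
  write_survival_csv(cv$os, p)
  back <- read_survival_csv(p)
  expect_equal(back$survival, cv$os$survival, tolerance = 1e-12)

  sc <- two_arm_flat_scenario()
  raw <- melcea:::scenario_to_list(sc)
  dir <- tempfile(); dir.create(dir)
  write_survival_csv(cv$os, file.path(dir, "os.csv"))
  write_survival_csv(cv$pfs, file.path(dir, "pfs.csv"))
  raw$survival$a <- list(os = list(csv = "os.csv"), pfs = list(csv = "pfs.csv"))
  spath <- file.path(dir, "scenario.yaml")
  yaml::write_yaml(raw, spath, precision = 15L)
  sc2 <- load_scenario(spath)
  expect_equal(sc2$survival$a$os$survival, cv$os$survival, tolerance = 1e-12)

  raw$survival$a$os$csv <- "missing.csv"
  yaml::write_yaml(raw, spath, precision = 15L)
  expect_error(load_scenario(spath), "missing.csv", class = "melcea_io_error")
})
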