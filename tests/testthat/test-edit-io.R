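# Studbook/pedigree I/O and the career editing rules.

sim_fixture <- local({
  sim <- NULL
  function() {
    if (is.null(sim)) {
      s <- simulate_pedigree(small_config(seed = 2))
      ev <- simulate_careers(s)
      sim <<- list(sim = s, events = ev)
    }
    sim
  }
})

test_that("studbook and pedigree files round-trip losslessly", {
  fx <- sim_fixture()
  sb <- withr::local_tempfile(fileext = ".csv")
  pd <- withr::local_tempfile(fileext = ".csv")
  write_studbook(fx$events, sb)
  write_pedigree(fx$sim$pedigree, pd)
  ev2 <- read_studbook(sb)
  ped2 <- read_pedigree(pd)
  cols <- c("mare_id", "event_year", "event_type", "age_months", "eu_id")
  orig <- fx$events[order(fx$events$mare_id, fx$events$event_year), cols]
  rownames(orig) <- NULL
  expect_equal(ev2[, cols], orig)
  expect_equal(ped2, fx$sim$pedigree[, c("animal", "sire", "dam",
                                         "birth_year", "sex")])
})

test_that("malformed studbook rows are rejected with line numbers", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mare_id,event_year,event_type,age_months,eu_id",
               "1,2000,F,38,1",
               "1,2001,X,50,1"), tf)
  expect_error(read_studbook(tf), "event_type.*line 3|invalid event_type")
  writeLines(c("mare_id,event_year,event_type,age_months,eu_id",
               "1,2000,F,38,1",
               "1,2000,O,39,1"), tf)
  expect_error(read_studbook(tf), "duplicate")
  writeLines(c("mare_id,event_year,event_type,age_months,eu_id",
               "1,2000,F,thirty,1"), tf)
  expect_error(read_studbook(tf), "age_months")
})

test_that("pedigree files with self-parents or cycles are rejected", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal,sire,dam,birth_year,sex",
               "1,1,0,1990,M"), tf)
  expect_error(read_pedigree(tf), "own parent")
  writeLines(c("animal,sire,dam,birth_year,sex",
               "1,2,0,1990,M",
               "2,1,0,1991,M"), tf)
  expect_error(read_pedigree(tf), "cycle")
})

test_that("editing rules discard the documented violations", {
  ped <- data.frame(animal = c(1:2, 10:13), sire = c(0, 0, 1, 1, 1, 0),
                    dam = c(0, 0, 2, 2, 2, 2), birth_year = c(1980, 1980,
                    rep(1995, 4)), sex = c("M", "F", rep("F", 4)))
  mk <- function(id, age1, types, years = NULL, ages = NULL) {
    L <- length(types)
    data.frame(mare_id = id,
               event_year = if (is.null(years)) 1998 + seq_len(L) else years,
               event_type = types,
               age_months = if (is.null(ages)) age1 + 12 * (seq_len(L) - 1)
                            else ages,
               eu_id = 1L)
  }
  ev <- rbind(
    mk(10, 30, rep("F", 6)),                     # first event at 30 months
    mk(11, 40, rep("F", 6),
       ages = c(40, 58, 70, 82, 94, 106)),       # 18-month foaling interval
    mk(12, 40, rep("F", 6)),                     # clean -> retained
    mk(13, 40, rep("F", 6))                      # unknown sire
  )
  out <- apply_editing(ev, ped, editing_rules(min_seasons = 6,
                                              min_eu_by_records = 1))
  expect_equal(out$mare_id, 12)
  rep_ <- attr(out, "edit_report")
  expect_equal(unname(rep_["first_event_age"]), 1)
  expect_equal(unname(rep_["foaling_interval"]), 1)
  expect_equal(unname(rep_["unknown_parent"]), 1)
  # foalings separated by an open season are not interval-constrained
  ev2 <- mk(12, 40, c("F", "O", "F", "F", "F", "F"))
  out2 <- apply_editing(ev2, ped, editing_rules(min_seasons = 6,
                                                min_eu_by_records = 1))
  expect_equal(out2$mare_id, 12)
})

test_that("filtering is monotone and the training set nests in the full set", {
  fx <- sim_fixture()
  r3 <- editing_rules(min_seasons = 3)
  r6 <- editing_rules(min_seasons = 6)
  full <- apply_editing(fx$events, fx$sim$pedigree, r3)
  training <- apply_editing(fx$events, fx$sim$pedigree, r6)
  expect_true(all(training$mare_id %in% full$mare_id))
  expect_lte(nrow(training), nrow(full))
  # tightening a rule never enlarges the output
  tight <- editing_rules(min_seasons = 3, max_first_event_age = 47)
  expect_lte(nrow(apply_editing(fx$events, fx$sim$pedigree, tight)),
             nrow(full))
  # every retained mare respects class and interval windows
  expect_true(all(full$af_class %in% c(3L, 4L)))
  iv <- full$min_interval[!is.na(full$min_interval)]
  expect_true(all(iv >= 11 & full$max_interval[!is.na(full$max_interval)] <= 17))
})

test_that("EU-BY levels count records and the sparse-level filter iterates", {
  fx <- sim_fixture()
  full <- apply_editing(fx$events, fx$sim$pedigree,
                        editing_rules(min_seasons = 3))
  eu <- build_eu_by(full)
  expect_equal(sum(eu$records), nrow(full))
  expect_true(all(eu$records >= 2))
  # two mares, same EU, different birth years -> 2 levels
  toy <- data.frame(eu_by = c("1:2000", "1:2001"))
  expect_equal(attr(build_eu_by(toy), "n_levels"), 2L)
})
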