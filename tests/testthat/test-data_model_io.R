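test_that("write then read is the identity on valid datasets", {
  for (d in list(toy_dataset(),
                 generate_cohort(list(cad_group_params(n = 5),
                                      con_group_params(n = 4)),
                                 seed = 11)$data)) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_study_dataset(d, path)
    back <- read_study_dataset(path)
    expect_equal(back$measurements, d$measurements, tolerance = 1e-12)
    expect_equal(back$participants, d$participants, tolerance = 1e-12)
  }
})

test_that("an empty dataset writes a header-only file", {
  d <- study_dataset(
    participants = tibble::tibble(participant_id = character(),
                                  group = character()),
    measurements = tibble::tibble(participant_id = character(),
                                  condition = character(),
                                  timepoint = character(),
                                  hr = numeric(), bsbp = numeric(),
                                  bdbp = numeric(), csbp = numeric(),
                                  cfpwv = numeric())
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_study_dataset(d, path)
  expect_length(readLines(path), 1L)
})

test_that("a 10-participant cohort writes 10 x 2 x 4 measurement rows", {
  d <- generate_cohort(list(cad_group_params(n = 10)), seed = 3)$data
  path <- withr::local_tempfile(fileext = ".csv")
  write_study_dataset(d, path)
  expect_length(readLines(path), 1L + 10 * 2 * 4)
})

test_that("validation rejects malformed input with typed errors", {
  base <- toy_dataset()

  m <- base$measurements
  m$bdbp[3] <- m$bsbp[3] + 5 # diastolic above systolic
  expect_error(study_dataset(base$participants, m),
               "row 3", class = "peh_error_integrity")

  m <- base$measurements
  m <- rbind(m, m[1, ]) # duplicate (participant, condition, timepoint)
  expect_error(study_dataset(base$participants, m),
               class = "peh_error_integrity")

  expect_error(
    study_dataset(base$participants,
                  base$measurements[setdiff(names(base$measurements), "csbp")]),
    "csbp", class = "peh_error_schema")

  m <- base$measurements
  m$participant_id[1] <- "ghost"
  expect_error(study_dataset(base$participants, m),
               "ghost", class = "peh_error_integrity")

  p <- base$participants
  p$group[1] <- "PATIENT"
  expect_error(study_dataset(p, base$measurements),
               "PATIENT", class = "peh_error_parse")

  m <- base$measurements
  m$timepoint[2] <- "P45"
  expect_error(study_dataset(base$participants, m),
               "P45", class = "peh_error_parse")
})

test_that("reading surfaces schema, parse and integrity problems by location", {
  path <- withr::local_tempfile(fileext = ".csv")

  writeLines(c("participant_id,group,condition,timepoint,hr,bsbp,bdbp,csbp",
               "p1,CAD,MOD,PRE,60,112,70,101",
               "p1,CAD,MOD,P15,64,110,seventy,99"), path)
  expect_error(read_study_dataset(path), "row 2",
               class = "peh_error_parse")

  writeLines(c("participant_id,group,condition,timepoint,hr,bsbp,bdbp,csbp",
               "p1,CAD,MOD,PRE,60,112,70,101",
               "p1,CAD,MOD,P15,64,110,115,99"), path)
  expect_error(read_study_dataset(path), "row 2",
               class = "peh_error_integrity")

  writeLines(c("participant_id,group,condition,timepoint,hr,bsbp,bdbp",
               "p1,CAD,MOD,PRE,60,112,70"), path)
  expect_error(read_study_dataset(path), "csbp",
               class = "peh_error_schema")
})

test_that("numeric minute timepoints and unknown columns are handled on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(
    c("participant_id,group,condition,timepoint,hr,bsbp,bdbp,csbp,operator",
      "p1,CAD,MOD,0,60,112,70,101,AB",
      "p1,CAD,MOD,15,64,110,69,99,AB",
      "p1,CAD,MOD,30,66,111,69,102,AB"), path)
  expect_warning(d <- read_study_dataset(path), "operator")
  expect_equal(d$measurements$timepoint, c("PRE", "P15", "P30"))
  expect_equal(nrow(d$measurements), 3L)
})

test_that("column mapping adapts foreign spreadsheet headers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID,grp,cond,minute,HR,SBP,DBP,cSBP",
               "p1,CAD,MOD,0,60,112,70,101",
               "p1,CAD,MOD,30,66,111,69,102"), path)
  d <- read_study_dataset(path, col_map = c(
    participant_id = "ID", group = "grp", condition = "cond",
    timepoint = "minute", hr = "HR", bsbp = "SBP", bdbp = "DBP",
    csbp = "cSBP"))
  expect_equal(d$measurements$bsbp, c(112, 111))
  expect_error(read_study_dataset(path, col_map = c(bsbp = "nope")),
               "nope", class = "peh_error_schema")
})

test_that("completeness requires PRE plus a 15- or 30-min value", {
  d <- toy_dataset()
  expect_setequal(complete_participants(d, "csbp", "MOD"), c("p1", "p2"))

  m <- d$measurements
  m$csbp[m$participant_id == "p2" & m$condition == "MOD" &
           m$timepoint %in% c("P15", "P30")] <- NA
  d2 <- study_dataset(d$participants, m)
  expect_equal(complete_participants(d2, "csbp", "MOD"), "p1")
  # PRE-only missingness also disqualifies
  m$csbp[m$participant_id == "p1" & m$condition == "MOD" &
           m$timepoint == "PRE"] <- NA
  d3 <- study_dataset(d$participants, m)
  expect_equal(complete_participants(d3, "csbp", "MOD"), character(0))
})
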