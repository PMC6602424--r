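non_modular <- setdiff(canonical_names(), "decay_chain_modular")

test_that("text format round-trips every catalogue model element-wise", {
  for (nm in canonical_names()) {
    m1 <- canonical(nm)
    m2 <- read_text(write_text(m1))
    if (inherits(m1, "ModularModel")) {
      expect_identical(names(m1$modules), names(m2$modules), info = nm)
      for (mod in names(m1$modules))
        expect_identical(m1$modules[[mod]]$model, m2$modules[[mod]]$model,
                         info = paste(nm, mod))
      expect_equal(length(m1$connections), length(m2$connections), info = nm)
    } else {
      expect_identical(m1$model, m2$model, info = nm)
    }
  }
})

test_that("SBML round-trips every non-modular catalogue model", {
  for (nm in non_modular) {
    m1 <- canonical(nm)
    m2 <- read_sbml(write_sbml(m1))
    expect_identical(m1$model, m2$model, info = nm)
    # second trip is a fixed point
    expect_identical(read_sbml(write_sbml(m2))$model, m2$model, info = nm)
  }
})

test_that("text and SBML readings of the same model agree element-wise", {
  for (nm in non_modular) {
    mt <- canonical(nm)
    ms <- read_sbml(write_sbml(mt))
    expect_identical(mt$model, ms$model, info = nm)
  }
})

test_that("minimal and structured SBML map onto the expected elements", {
  xml <- paste0(
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" ',
    'level="3" version="2"><model id="m1"><listOfSpecies>',
    '<species id="X" initialAmount="2" boundaryCondition="false" ',
    'constant="false"/></listOfSpecies></model></sbml>')
  m <- read_sbml(xml)
  expect_length(m$model$variables, 1L)
  expect_length(m$model$reactions, 0L)
  expect_equal(m$model$variables$X$initial_value, 2)

  m2 <- canonical("decay")
  got <- read_sbml(write_sbml(m2))
  expect_identical(got$model$reactions$J1$reactants, c(A = 1))
  expect_true(sbkernel:::expr_equal(got$model$reactions$J1$kinetic_law,
                                    quote(k * A)))
})

test_that("unsupported SBML constructs raise import errors naming them", {
  comp <- paste0(
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" ',
    'xmlns:comp="http://www.sbml.org/sbml/level3/version1/comp/version1" ',
    'level="3" version="2"><model id="m"/></sbml>')
  expect_error(read_sbml(comp), "comp")
  fd <- paste0(
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" ',
    'level="3" version="2"><model id="m"><listOfFunctionDefinitions>',
    '<functionDefinition id="f"/></listOfFunctionDefinitions>',
    '</model></sbml>')
  expect_error(read_sbml(fd), "functionDefinition")
  expect_error(read_sbml("<notsbml/>"), "not an SBML")
  # modular models cannot be exported as core SBML
  expect_error(write_sbml(canonical("decay_chain_modular")), "flatten")
})

test_that("concentration-initialized species convert through compartment size", {
  xml <- paste0(
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" ',
    'level="3" version="2"><model id="m">',
    '<listOfCompartments><compartment id="cell" size="2" constant="true"/>',
    '</listOfCompartments><listOfSpecies>',
    '<species id="X" compartment="cell" initialConcentration="3"/>',
    '</listOfSpecies></model></sbml>')
  m <- read_sbml(xml)
  expect_equal(m$model$variables$X$initial_value, 6)  # amount = conc * size
})

test_that("initial assignments fold into initial values at load", {
  xml <- paste0(
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" ',
    'level="3" version="2"><model id="m"><listOfSpecies>',
    '<species id="X" initialAmount="1"/></listOfSpecies>',
    '<listOfParameters><parameter id="a" value="4" constant="true"/>',
    '</listOfParameters><listOfInitialAssignments>',
    '<initialAssignment symbol="X">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML">',
    '<apply><times/><ci>a</ci><cn type="integer">2</cn></apply>',
    '</math></initialAssignment></listOfInitialAssignments></model></sbml>')
  expect_equal(read_sbml(xml)$model$variables$X$initial_value, 8)
})

test_that("the text grammar covers the documented statement forms", {
  m <- read_text(c("J1: A -> B; k*A", "A = 1", "k = 1"))
  expect_length(m$model$variables, 2L)
  expect_length(m$model$reactions, 1L)
  expect_identical(names(m$model$parameters), "k")

  mm <- canonical("decay_chain_modular")
  expect_s3_class(mm, "ModularModel")
  expect_length(mm$modules, 2L)
  expect_length(mm$connections, 1L)

  expect_error(read_text(c("J1: A -> B; k*A", "what is this")), "line 2")
  expect_error(read_text("A = blue"), "not a number")
})

test_that("time-course tables read with missing cells and strict checks", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,A,B", "0,1,5", "0.5,,4", "1,0.37,3"), tf)
  ex <- read_timecourse(tf)
  expect_equal(nrow(ex$data), 3L)
  expect_true(is.na(ex$data$A[2]))         # blank cell flagged, row kept
  expect_identical(ex$observed, c("A", "B"))

  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("time\tA", "0\t1", "1\t2"), tf2)
  expect_equal(read_timecourse(tf2)$data$A, c(1, 2))   # tab auto-detected

  tf3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,A", "0,1", "0,2"), tf3)
  expect_error(read_timecourse(tf3), "duplicate time")
  tf4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,A", "0,one"), tf4)
  expect_error(read_timecourse(tf4), "non-numeric")

  tf5 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("A,B", "1,2"), tf5)
  ss <- read_timecourse(tf5, steady_state = TRUE)
  expect_identical(ss$kind, "steady_state")
})
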