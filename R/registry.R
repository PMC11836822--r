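# Linked registry container: readers, writers, validation, anonymization.
#
# A registry bundles six event tables in the shape of national cattle
# registry extracts: per-animal records, farm stays, calvings, bulk-milk
# tests, antibiotic prescriptions and the farm register. Files are UTF-8
# comma-delimited with a header row and ISO-8601 dates; an empty exit_date
# means the animal is still present at the end of observation.

REGISTRY_TABLES <- c("animals", "stays", "calvings", "milk_tests",
                     "prescriptions", "farms")

registry_schema <- function() {
  list(
    animals = list(
      cols  = c("animal_id", "birth_date", "sex", "breed_category",
                "birth_farm_id"),
      dates = "birth_date",
      cats  = list(sex = SEXES, breed_category = BREED_CATEGORIES)),
    stays = list(
      cols  = c("animal_id", "farm_id", "entry_date", "exit_date",
                "entry_mode", "exit_mode", "origin_farm_id",
                "destination_farm_id"),
      dates = c("entry_date", "exit_date"),
      cats  = list(entry_mode = ENTRY_MODES, exit_mode = EXIT_MODES)),
    calvings = list(
      cols  = c("animal_id", "date", "stillbirth"),
      dates = "date",
      cats  = list()),
    milk_tests = list(
      cols  = c("farm_id", "date"),
      dates = "date",
      cats  = list()),
    prescriptions = list(
      cols  = c("farm_id", "date", "usage_category"),
      dates = "date",
      cats  = list(usage_category = USAGE_CATEGORIES)),
    farms = list(
      cols  = c("farm_id", "facility_type"),
      dates = character(),
      cats  = list(facility_type = FACILITY_TYPES))
  )
}

#' Assemble a linked registry from six tables
#'
#' Coerces the tables to `data.table`, normalises column types and runs full
#' validation (closed categorical sets, date sanity, stay invariants,
#' referential integrity).
#'
#' @param animals,stays,calvings,milk_tests,prescriptions,farms Data frames
#'   following the registry schema. Missing arguments default to empty
#'   tables.
#' @return A validated `linked_registry` object (a named list of the six
#'   `data.table`s).
#' @export
linked_registry <- function(animals = NULL, stays = NULL, calvings = NULL,
                            milk_tests = NULL, prescriptions = NULL,
                            farms = NULL) {
  sch <- registry_schema()
  empty_tbl <- function(tab) {
    spec <- sch[[tab]]
    out <- lapply(spec$cols, function(cl) {
      if (cl %in% spec$dates) as.Date(character()) else
        if (tab == "calvings" && cl == "stillbirth") logical() else character()
    })
    names(out) <- spec$cols
    as.data.table(out)
  }
  reg <- list(animals = animals, stays = stays, calvings = calvings,
              milk_tests = milk_tests, prescriptions = prescriptions,
              farms = farms)
  for (tab in REGISTRY_TABLES) {
    if (is.null(reg[[tab]]) || nrow(reg[[tab]]) == 0L) {
      reg[[tab]] <- empty_tbl(tab)
    } else {
      reg[[tab]] <- normalize_table(as.data.table(reg[[tab]]), tab)
    }
  }
  class(reg) <- "linked_registry"
  validate_registry(reg)
  reg
}

normalize_table <- function(dt, tab) {
  spec <- registry_schema()[[tab]]
  missing_cols <- setdiff(spec$cols, names(dt))
  if (length(missing_cols)) {
    stop(sprintf("table '%s' is missing column(s): %s", tab,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  dt <- dt[, spec$cols, with = FALSE]
  for (cl in spec$dates) {
    v <- dt[[cl]]
    if (!inherits(v, "Date")) {
      ch <- as.character(v)
      ch[!is.na(ch) & ch == ""] <- NA_character_
      parsed <- as.Date(ch, format = "%Y-%m-%d")
      bad <- which(!is.na(ch) & is.na(parsed))
      if (length(bad)) {
        stop(sprintf("table '%s', column '%s': malformed date at row %d ('%s')",
                     tab, cl, bad[1], ch[bad[1]]), call. = FALSE)
      }
      data.table::set(dt, j = cl, value = parsed)
    }
  }
  if (tab == "calvings") {
    v <- dt[["stillbirth"]]
    if (!is.logical(v)) {
      data.table::set(dt, j = "stillbirth",
                      value = as.logical(toupper(as.character(v))))
    }
  }
  for (cl in setdiff(spec$cols, c(spec$dates, "stillbirth"))) {
    v <- dt[[cl]]
    if (!is.character(v)) data.table::set(dt, j = cl, value = as.character(v))
  }
  # optional id columns: empty string -> NA
  for (cl in intersect(c("origin_farm_id", "destination_farm_id"), names(dt))) {
    v <- dt[[cl]]
    v[!is.na(v) & v == ""] <- NA_character_
    data.table::set(dt, j = cl, value = v)
  }
  dt
}

#' Validate a linked registry
#'
#' Checks closed categorical sets, per-row stay invariants (entry before
#' exit, movement ids consistent with entry/exit modes, non-overlapping
#' stays per animal) and referential integrity between tables. Errors cite
#' the offending table and row.
#'
#' @param registry A `linked_registry`.
#' @return The registry, invisibly, if valid.
#' @export
validate_registry <- function(registry) {
  stopifnot(inherits(registry, "linked_registry"))
  sch <- registry_schema()
  fail <- function(tab, row, msg) {
    stop(sprintf("registry validation: table '%s', row %d: %s", tab, row, msg),
         call. = FALSE)
  }
  for (tab in REGISTRY_TABLES) {
    dt <- registry[[tab]]
    spec <- sch[[tab]]
    for (cl in names(spec$cats)) {
      bad <- which(!is.na(dt[[cl]]) & !(dt[[cl]] %chin% spec$cats[[cl]]))
      if (length(bad)) {
        fail(tab, bad[1], sprintf("value '%s' of '%s' not in {%s}",
                                  dt[[cl]][bad[1]], cl,
                                  paste(spec$cats[[cl]], collapse = ", ")))
      }
    }
    mandatory <- setdiff(spec$cols, c("origin_farm_id", "destination_farm_id",
                                      "exit_date"))
    for (cl in mandatory) {
      bad <- which(is.na(dt[[cl]]))
      if (length(bad)) fail(tab, bad[1], sprintf("missing value in '%s'", cl))
    }
  }
  an <- registry$animals
  if (anyDuplicated(an$animal_id)) {
    fail("animals", anyDuplicated(an$animal_id), "duplicate animal_id")
  }
  st <- registry$stays
  if (nrow(st)) {
    bad <- which(!is.na(st$exit_date) & st$entry_date > st$exit_date)
    if (length(bad)) fail("stays", bad[1], "entry_date after exit_date")
    bad <- which(st$exit_mode == "slaughter" & !is.na(st$destination_farm_id))
    if (length(bad)) fail("stays", bad[1],
                          "slaughter exit must not carry a destination farm")
    bad <- which(st$exit_mode == "move_out" & is.na(st$destination_farm_id))
    if (length(bad)) fail("stays", bad[1],
                          "move_out exit requires destination_farm_id")
    bad <- which(st$entry_mode == "move_in" & is.na(st$origin_farm_id))
    if (length(bad)) fail("stays", bad[1],
                          "move_in entry requires origin_farm_id")
    bad <- which(st$exit_mode == "none" & !is.na(st$exit_date))
    if (length(bad)) fail("stays", bad[1],
                          "open stay (exit_mode none) must have empty exit_date")
    bad <- which(st$exit_mode != "none" & is.na(st$exit_date))
    if (length(bad)) fail("stays", bad[1],
                          "closed stay requires an exit_date")
    # overlapping stays of the same animal (half-open intervals may share ends)
    idx <- order(st$animal_id, st$entry_date)
    aid <- st$animal_id[idx]
    en <- as.integer(st$entry_date)[idx]
    ex <- as.integer(st$exit_date)[idx]
    ex[is.na(ex)] <- .Machine$integer.max
    n <- length(aid)
    if (n > 1L) {
      same <- aid[-1L] == aid[-n]
      olap <- which(same & en[-1L] < ex[-n])
      if (length(olap)) {
        fail("stays", idx[olap[1] + 1L],
             sprintf("overlapping stays for animal '%s'", aid[olap[1] + 1L]))
      }
    }
    miss <- which(!(st$animal_id %chin% an$animal_id))
    if (length(miss)) fail("stays", miss[1],
                           sprintf("animal_id '%s' not in animals table",
                                   st$animal_id[miss[1]]))
    missf <- which(!(st$farm_id %chin% registry$farms$farm_id))
    if (length(missf)) fail("stays", missf[1],
                            sprintf("farm_id '%s' not in farms table",
                                    st$farm_id[missf[1]]))
  }
  cv <- registry$calvings
  if (nrow(cv)) {
    miss <- which(!(cv$animal_id %chin% an$animal_id))
    if (length(miss)) fail("calvings", miss[1], "animal_id not in animals table")
    bd <- an$birth_date[match(cv$animal_id, an$animal_id)]
    bad <- which(cv$date < bd)
    if (length(bad)) fail("calvings", bad[1], "calving before dam's birth date")
  }
  for (tab in c("milk_tests", "prescriptions")) {
    dt <- registry[[tab]]
    if (nrow(dt)) {
      miss <- which(!(dt$farm_id %chin% registry$farms$farm_id))
      if (length(miss)) fail(tab, miss[1], "farm_id not in farms table")
    }
  }
  invisible(registry)
}

#' Read a linked registry from delimited files
#'
#' @param paths Named character vector or list with one path per table
#'   (`animals`, `stays`, `calvings`, `milk_tests`, `prescriptions`,
#'   `farms`), or a single directory containing `<table>.csv` files.
#' @return A validated `linked_registry`.
#' @export
read_registry <- function(paths) {
  if (is.character(paths) && length(paths) == 1L && dir.exists(paths)) {
    paths <- setNames(file.path(paths, paste0(REGISTRY_TABLES, ".csv")),
                      REGISTRY_TABLES)
  }
  paths <- as.list(paths)
  missing_tab <- setdiff(REGISTRY_TABLES, names(paths))
  if (length(missing_tab)) {
    stop("read_registry: no path given for table(s): ",
         paste(missing_tab, collapse = ", "), call. = FALSE)
  }
  tabs <- lapply(REGISTRY_TABLES, function(tab) {
    p <- paths[[tab]]
    if (!file.exists(p)) {
      stop(sprintf("read_registry: file for table '%s' not found: %s", tab, p),
           call. = FALSE)
    }
    dt <- data.table::fread(p, colClasses = "character", na.strings = NULL,
                            keepLeadingZeros = TRUE)
    sch <- registry_schema()[[tab]]
    if (!identical(sort(names(dt)), sort(sch$cols)) && nrow(dt) == 0L &&
        ncol(dt) == 0L) {
      # fread of a header-only file still yields the header; a fully empty
      # file is rejected below via the missing-column check
      dt <- as.data.table(setNames(rep(list(character()), length(sch$cols)),
                                   sch$cols))
    }
    dt
  })
  names(tabs) <- REGISTRY_TABLES
  do.call(linked_registry, tabs)
}

#' Write a linked registry to delimited files
#'
#' One UTF-8 comma-delimited file per table with ISO-8601 dates and stable
#' column order; open exit dates are written as empty fields.
#'
#' @param registry A `linked_registry`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of written file paths.
#' @export
write_registry <- function(registry, dir) {
  stopifnot(inherits(registry, "linked_registry"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("write_registry: cannot create directory: ", dir,
                  call. = FALSE)
  }
  out <- setNames(file.path(dir, paste0(REGISTRY_TABLES, ".csv")),
                  REGISTRY_TABLES)
  for (tab in REGISTRY_TABLES) {
    data.table::fwrite(registry[[tab]], out[[tab]], dateTimeAs = "ISO",
                       na = "", quote = FALSE)
  }
  invisible(out)
}

#' Anonymize farm and animal identifiers
#'
#' Replaces every farm identifier (including origin, destination and birth
#' farms that only appear as movement counterparts) and every animal
#' identifier by opaque tokens, preserving the relational structure: any
#' join that held before holds after under the returned mapping.
#'
#' @param registry A `linked_registry`.
#' @param seed Integer seed controlling the token permutation.
#' @return A list with elements `registry` (anonymized) and `mapping`
#'   (list of two data.tables `farms` and `animals` with columns
#'   `original`, `token`).
#' @export
anonymize <- function(registry, seed = 1L) {
  stopifnot(inherits(registry, "linked_registry"))
  farm_ids <- sort(unique(c(registry$farms$farm_id, registry$stays$farm_id,
                            registry$stays$origin_farm_id,
                            registry$stays$destination_farm_id,
                            registry$animals$birth_farm_id,
                            registry$milk_tests$farm_id,
                            registry$prescriptions$farm_id)))
  farm_ids <- farm_ids[!is.na(farm_ids)]
  animal_ids <- sort(unique(registry$animals$animal_id))
  rng <- local({set.seed(as.integer(seed) %% .Machine$integer.max); NULL})
  farm_tok <- sprintf("F%06d", sample.int(length(farm_ids)))
  animal_tok <- sprintf("A%08d", sample.int(max(length(animal_ids), 1L)))[
    seq_along(animal_ids)]
  fmap <- setNames(farm_tok, farm_ids)
  amap <- setNames(animal_tok, animal_ids)
  remap <- function(x, mp) {
    out <- unname(mp[x])
    out[is.na(x)] <- NA_character_
    out
  }
  reg <- lapply(unclass(registry), copy)
  reg$animals[, `:=`(animal_id = remap(animal_id, amap),
                     birth_farm_id = remap(birth_farm_id, fmap))]
  reg$stays[, `:=`(animal_id = remap(animal_id, amap),
                   farm_id = remap(farm_id, fmap),
                   origin_farm_id = remap(origin_farm_id, fmap),
                   destination_farm_id = remap(destination_farm_id, fmap))]
  reg$calvings[, animal_id := remap(animal_id, amap)]
  reg$milk_tests[, farm_id := remap(farm_id, fmap)]
  reg$prescriptions[, farm_id := remap(farm_id, fmap)]
  reg$farms[, farm_id := remap(farm_id, fmap)]
  class(reg) <- "linked_registry"
  validate_registry(reg)
  list(registry = reg,
       mapping = list(
         farms = data.table(original = farm_ids, token = unname(fmap)),
         animals = data.table(original = animal_ids, token = unname(amap))))
}

#' @export
print.linked_registry <- function(x, ...) {
  cat("<linked_registry>\n")
  for (tab in REGISTRY_TABLES) {
    cat(sprintf("  %-13s %8d rows\n", tab, nrow(x[[tab]])))
  }
  invisible(x)
}
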