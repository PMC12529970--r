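#' @name data_core
#' @title Inventory tables, growth stages and data partitioning
#' @description
#' An inventory table is a plain `data.frame` with one row per tree and the
#' canonical columns `region`, `plot`, `tree`, `dbh_cm`, `lh_m`, `lcd_m`,
#' `density_ha`, `age_y`. Plots are nested in regions: a `plot` id is unique
#' within its `region`. All fitting functions in the package consume this
#' layout.
NULL

#' Canonical inventory column names
#' @return Character vector of the eight required column names, in order.
#' @export
inventory_columns <- function() {
  c("region", "plot", "tree", "dbh_cm", "lh_m", "lcd_m", "density_ha", "age_y")
}

#' Growth-stage levels for Chinese fir
#'
#' Five ordinal age classes used throughout: young (1-10 y), middle-aged
#' (11-20 y), near-mature (21-25 y), mature (26-36 y), overmature (> 36 y).
#'
#' @return Character vector of the five stage labels, young to overmature.
#' @export
stage_levels <- function() {
  c("young", "middle_aged", "near_mature", "mature", "overmature")
}

#' Assign growth stage from tree age
#'
#' Deterministic mapping of age in years onto the five growth stages of a
#' fast-growing conifer plantation. Boundary ages (10, 20, 25, 36) belong to
#' the lower-named class; ages above 36 are overmature.
#'
#' @param age_y Integer vector of ages in years, all `>= 1`.
#' @return Ordered factor with levels [stage_levels()].
#' @examples
#' assign_growth_stage(c(8, 25, 26, 37))
#' @export
assign_growth_stage <- function(age_y) {
  if (length(age_y) == 0L) {
    return(factor(character(), levels = stage_levels(), ordered = TRUE))
  }
  if (any(!is.finite(age_y)) || any(age_y < 1)) {
    stop("age_y must be finite and >= 1")
  }
  cut(age_y, breaks = c(0, 10, 20, 25, 36, Inf),
      labels = stage_levels(), right = TRUE, ordered_result = TRUE)
}

#' Validate an inventory table
#'
#' Checks the structural invariants of an inventory table and collects (but
#' does not drop) violating rows: DBH below the 5 cm inventory threshold,
#' heights at or below breast height (unusable for model forms containing the
#' term H - 1.3), non-positive density, ages below 1, negative crown widths,
#' and missing values.
#'
#' @param table Inventory data.frame.
#' @return A list with `n_records`, `n_regions`, `n_plots`, and a
#'   `violations` data.frame (`row`, `field`, `issue`).
#' @export
validate_inventory <- function(table) {
  req <- inventory_columns()
  missing <- setdiff(req, names(table))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(table) == 0L) stop("inventory table has no rows")

  viol <- list()
  flag <- function(idx, field, issue) {
    if (any(idx)) {
      viol[[length(viol) + 1L]] <<- data.frame(
        row = which(idx), field = field, issue = issue,
        stringsAsFactors = FALSE)
    }
  }
  num_fields <- c("dbh_cm", "lh_m", "lcd_m", "density_ha", "age_y")
  for (f in num_fields) {
    flag(!is.finite(suppressWarnings(as.numeric(table[[f]]))),
         f, "missing or non-numeric")
  }
  dbh <- suppressWarnings(as.numeric(table$dbh_cm))
  flag(is.finite(dbh) & dbh < 5, "dbh_cm", "below 5 cm inventory threshold")
  lh <- suppressWarnings(as.numeric(table$lh_m))
  flag(is.finite(lh) & lh <= 1.3, "lh_m",
       "height <= 1.3 m, unusable for (H - 1.3) model forms")
  lcd <- suppressWarnings(as.numeric(table$lcd_m))
  flag(is.finite(lcd) & lcd < 0, "lcd_m", "negative crown width")
  dens <- suppressWarnings(as.numeric(table$density_ha))
  flag(is.finite(dens) & dens <= 0, "density_ha", "non-positive density")
  age <- suppressWarnings(as.numeric(table$age_y))
  flag(is.finite(age) & age < 1, "age_y", "age below 1 year")

  plot_key <- paste(table$region, table$plot, sep = "\r")
  # every plot id maps to exactly one region (nestedness is encoded by the
  # composite key, so this only fails if a bare plot id is reused with NA)
  list(
    n_records = nrow(table),
    n_regions = length(unique(table$region)),
    n_plots = length(unique(plot_key)),
    violations = if (length(viol)) do.call(rbind, viol) else
      data.frame(row = integer(), field = character(), issue = character(),
                 stringsAsFactors = FALSE)
  )
}

#' Read an inventory table from delimited text
#'
#' Reads a comma- (default) or tab-delimited file with a header, coerces the
#' eight canonical columns, and attaches a validation report. Rows violating
#' inventory invariants are flagged in the report, never dropped.
#'
#' @param path Path to the delimited text file.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @param col_map Optional named character vector mapping canonical names to
#'   the file's header names, e.g. `c(dbh_cm = "DBH")`. Unmapped columns must
#'   already use canonical names.
#' @return Inventory data.frame with attribute `"validation"` holding the
#'   [validate_inventory()] report.
#' @export
read_inventory <- function(path, sep = ",", col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty inventory file: ", path)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(raw)) stop("mapped column not in file: ", src)
      names(raw)[names(raw) == src] <- canon
    }
  }
  missing <- setdiff(inventory_columns(), names(raw))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  tab <- raw[inventory_columns()]
  tab$region <- as.character(tab$region)
  tab$plot <- as.character(tab$plot)
  tab$tree <- suppressWarnings(as.integer(tab$tree))
  for (f in c("dbh_cm", "lh_m", "lcd_m", "density_ha", "age_y")) {
    tab[[f]] <- suppressWarnings(as.numeric(tab[[f]]))
  }
  attr(tab, "validation") <- validate_inventory(tab)
  tab
}

#' Write an inventory table to delimited text
#'
#' Numeric fields are written with 17 significant digits so that
#' write-then-read round-trips reproduce every value to full double
#' precision.
#'
#' @param table Inventory data.frame.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_inventory <- function(table, path, sep = ",") {
  out <- table[inventory_columns()]
  for (f in c("dbh_cm", "lh_m", "lcd_m", "density_ha", "age_y")) {
    out[[f]] <- sprintf("%.17g", out[[f]])
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Random train/test partition of an inventory
#'
#' Splits an inventory into a model-fitting set and an independent validation
#' set. With `unit = "tree"` (default, matching the common inventory
#' practice) individual trees are sampled, and the training size is
#' `fraction * n` rounded half-up; with `unit = "plot"` whole plots are
#' sampled, which avoids leaking within-plot information between the sets.
#'
#' @param table Inventory data.frame.
#' @param fraction Training fraction, strictly between 0 and 1.
#' @param seed Integer seed; identical seeds give identical partitions.
#' @param unit `"tree"` or `"plot"`.
#' @return List with components `train` and `test`; the two are disjoint and
#'   their union is the input.
#' @export
split_train_test <- function(table, fraction = 0.7, seed = 1L,
                             unit = c("tree", "plot")) {
  unit <- match.arg(unit)
  if (nrow(table) == 0L) stop("inventory table has no rows")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("fraction must lie strictly between 0 and 1")
  }
  n <- nrow(table)
  idx <- with_seed(seed, {
    if (unit == "tree") {
      n_train <- round_half_up(fraction * n)
      sort(sample.int(n, n_train))
    } else {
      key <- paste(table$region, table$plot, sep = "\r")
      plots <- unique(key)
      n_train_plots <- round_half_up(fraction * length(plots))
      keep <- sample(plots, n_train_plots)
      which(key %in% keep)
    }
  })
  list(train = table[idx, , drop = FALSE],
       test = table[setdiff(seq_len(n), idx), , drop = FALSE])
}
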