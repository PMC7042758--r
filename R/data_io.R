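# Input tables and the grouping / filtering / area-assignment rules that
# turn raw ringing records into the model's count matrices.

#' Assign a ringing record to one of the eight marking groups
#'
#' Swedish and Finnish records map to `SWE` / `FIN` regardless of season or
#' age.  Records from the central (northern Germany, >= 52 N) and southern
#' (southern Germany and Switzerland) European regions are split by season:
#' full-grown birds ringed March--May form the spring-migration group,
#' chicks plus full-grown birds ringed June--July the breeding group, and
#' chicks plus full-grown birds ringed August--October the autumn group.
#' Chicks ringed outside August--October fall to the breeding group (chicks
#' are local by definition); a full-grown central/southern record ringed
#' November--February belongs to no group and raises an error.
#'
#' @param age `"chick"` or `"full_grown"` (vectorized).
#' @param month Ringing month, integer 1--12.
#' @param region One of `"Sweden"`, `"Finland"`, `"NorthernGermany"`,
#'   `"SouthernGermanySwitzerland"`; alternatively `"Germany"` (requires
#'   `lat`, split at `config$lat_split`, north-inclusive) or
#'   `"Switzerland"`.
#' @param lat Ringing latitude, only needed when `region == "Germany"`.
#' @param config A [mc_config()].
#' @return Character vector of group labels (see [group_labels()]).
#' @examples
#' assign_group("full_grown", 4, "SouthernGermanySwitzerland")  # spring
#' assign_group("chick", 6, "Germany", lat = 53.5)              # Central_breeding
#' assign_group("full_grown", 9, "Sweden")                      # SWE
#' @export
assign_group <- function(age, month, region, lat = NULL, config = mc_config()) {
  n <- max(length(age), length(month), length(region))
  age <- rep_len(as.character(age), n)
  month <- rep_len(as.integer(month), n)
  region <- rep_len(as.character(region), n)
  if (!is.null(lat)) lat <- rep_len(as.numeric(lat), n)
  ok_age <- c("chick", "full_grown")
  if (!all(age %in% ok_age)) stop("age must be 'chick' or 'full_grown'")
  if (any(is.na(month) | month < 1L | month > 12L)) stop("ringing month must be 1..12")
  ok_reg <- c("Sweden", "Finland", "NorthernGermany", "SouthernGermanySwitzerland",
              "Germany", "Switzerland")
  if (!all(region %in% ok_reg)) {
    stop("unknown region: ", paste(unique(setdiff(region, ok_reg)), collapse = ", "))
  }

  prefix <- rep(NA_character_, n)
  prefix[region == "NorthernGermany"] <- "Central"
  prefix[region == "SouthernGermanySwitzerland"] <- "Southern"
  prefix[region == "Switzerland"] <- "Southern"
  de <- region == "Germany"
  if (any(de)) {
    if (is.null(lat) || anyNA(lat[de])) {
      stop("region 'Germany' requires a ringing latitude to split at ",
           config$lat_split, " N")
    }
    prefix[de] <- ifelse(lat[de] >= config$lat_split, "Central", "Southern")
  }

  out <- rep(NA_character_, n)
  out[region == "Sweden"] <- "SWE"
  out[region == "Finland"] <- "FIN"

  cs <- is.na(out) # central/southern records, split by season
  season <- rep(NA_character_, n)
  fg <- age == "full_grown"
  season[cs & fg & month %in% config$spring_months] <- "spring"
  season[cs & fg & month %in% config$breeding_months] <- "breeding"
  season[cs & fg & month %in% config$autumn_months] <- "autumn"
  if (config$chick_autumn_rule) {
    season[cs & !fg] <- ifelse(month[cs & !fg] %in% config$autumn_months,
                               "autumn", "breeding")
  } else {
    season[cs & !fg] <- "breeding"
  }
  if (any(cs & is.na(season))) {
    bad <- which(cs & is.na(season))[1L]
    stop("unassignable record: full-grown bird ringed in month ", month[bad],
         " in the central/southern region (no group defined)")
  }
  out[cs] <- paste(prefix[cs], season[cs], sep = "_")
  stopifnot(all(out %in% group_labels()))
  out
}

#' Assign coordinates to a wintering area
#'
#' Rectangular approximation of the four sub-Saharan wintering areas:
#' everything at/south of `southern_lat` (-15.4) is Southern Africa; north
#' of it, longitude at/west of `west_central_lon` is Western Africa, then
#' Central Africa up to (and including) `rift_lon`, then Eastern Africa.
#' Points north of `sahara_lat` are `"outside"` the wintering domain.
#'
#' @param lat,lon Decimal degrees (vectorized).
#' @param config A [mc_config()] holding the boundary coordinates.
#' @return Character vector over `c(area_labels(), "outside")`.
#' @examples
#' assign_wintering_area(-20, 25)   # Southern
#' assign_wintering_area(-2, 18)    # Central
#' @export
assign_wintering_area <- function(lat, lon, config = mc_config()) {
  n <- max(length(lat), length(lon))
  lat <- rep_len(as.numeric(lat), n)
  lon <- rep_len(as.numeric(lon), n)
  if (any(abs(lat) > 90, na.rm = TRUE)) stop("latitude outside [-90, 90]")
  if (any(abs(lon) > 180, na.rm = TRUE)) stop("longitude outside [-180, 180]")
  out <- rep("outside", n)
  inside <- !is.na(lat) & !is.na(lon) & lat <= config$sahara_lat
  south <- inside & lat <= config$southern_lat
  out[south] <- "Southern"
  north <- inside & !south
  out[north & lon <= config$west_central_lon] <- "Western"
  out[north & lon > config$west_central_lon & lon <= config$rift_lon] <- "Central"
  out[north & lon > config$rift_lon] <- "Eastern"
  out
}

#' Validate a table of raw ringing records
#'
#' @param records Data frame with columns `ring_id`, `age_at_ringing`,
#'   `ringing_date`, `ringing_lat`, `ringing_lon` and (possibly `NA`)
#'   `reencounter_date`, `reencounter_lat`, `reencounter_lon`.  Dates may be
#'   `Date` or ISO strings.
#' @return The records with dates coerced to `Date`, invisibly checked.
#' @export
validate_ringing_records <- function(records) {
  need <- c("ring_id", "age_at_ringing", "ringing_date", "ringing_lat",
            "ringing_lon", "reencounter_date", "reencounter_lat",
            "reencounter_lon")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing record columns: ", paste(miss, collapse = ", "))
  records$ringing_date <- as.Date(records$ringing_date)
  records$reencounter_date <- as.Date(records$reencounter_date)
  if (any(!records$age_at_ringing %in% c("chick", "full_grown"))) {
    stop("age_at_ringing must be 'chick' or 'full_grown'")
  }
  late <- !is.na(records$reencounter_date) &
    records$reencounter_date < records$ringing_date
  if (any(late)) {
    stop("reencounter before ringing for ring_id ",
         records$ring_id[which(late)[1L]])
  }
  for (col in c("ringing_lat", "reencounter_lat")) {
    if (any(abs(records[[col]]) > 90, na.rm = TRUE)) stop(col, " outside [-90, 90]")
  }
  for (col in c("ringing_lon", "reencounter_lon")) {
    if (any(abs(records[[col]]) > 180, na.rm = TRUE)) stop(col, " outside [-180, 180]")
  }
  records
}

#' Keep only wintering-season reencounters inside the wintering domain
#'
#' Retains records whose reencounter month lies in the wintering window
#' (November--February by default) and whose reencounter position maps to
#' one of the four sub-Saharan areas.  Records never reencountered are
#' dropped (they enter the model only through the numbers ringed).
#'
#' @inheritParams validate_ringing_records
#' @param config A [mc_config()].
#' @return The retained records with an `area` column appended.
#' @export
filter_wintering_reencounters <- function(records, config = mc_config()) {
  records <- validate_ringing_records(records)
  has <- !is.na(records$reencounter_date) &
    !is.na(records$reencounter_lat) & !is.na(records$reencounter_lon)
  month <- as.integer(format(records$reencounter_date, "%m"))
  in_window <- has & month %in% config$winter_months
  area <- rep(NA_character_, nrow(records))
  area[has] <- assign_wintering_area(records$reencounter_lat[has],
                                     records$reencounter_lon[has], config)
  keep <- in_window & !is.na(area) & area != "outside"
  out <- records[keep, , drop = FALSE]
  out$area <- area[keep]
  out
}

# ---- ReencounterData --------------------------------------------------------

#' Construct a validated set of ring-reencounter count matrices
#'
#' Holds, per age class (ringed as chick = `juv`, ringed full-grown = `ad`),
#' an 8x5 matrix of reencounter counts for the groups with known numbers
#' ringed (four wintering areas plus the never-reencountered complement
#' `N_i - sum_k R_ik`) and an 8x4 matrix for the groups/periods where the
#' number ringed is unknown.  All-zero unknown-total rows carry no
#' likelihood information and are flagged.
#'
#' @param R_ad_known,R_juv_known 8x4 nonnegative integer matrices of
#'   reencounter counts for records with known ringed totals (the
#'   never-reencountered column is derived, or an 8x5 matrix may be given
#'   directly).
#' @param N_ad,N_juv Length-8 numbers ringed per group for the known-total
#'   records.
#' @param R_ad_unknown,R_juv_unknown 8x4 count matrices for records with
#'   unknown ringed totals.
#' @return An object of class `reencounter_data`.
#' @export
reencounter_data <- function(R_ad_known, N_ad, R_juv_known, N_juv,
                             R_ad_unknown, R_juv_unknown) {
  pad <- function(R, N, what) {
    R <- as.matrix(R)
    if (ncol(R) == 5L) {
      N_implied <- rowSums(R)
      if (!missing(N) && !is.null(N) && any(N_implied != N)) {
        stop(what, ": row sums of the 5-column matrix disagree with N")
      }
      N <- N_implied
      R4 <- R[, 1:4, drop = FALSE]
    } else if (ncol(R) == 4L) {
      R4 <- R
    } else stop(what, " must have 4 or 5 columns")
    check_counts(R4, what)
    N <- as.numeric(N)
    if (length(N) != nrow(R4)) stop(what, ": N has wrong length")
    if (any(N < 0) || any(N != round(N))) stop(what, ": N must be nonnegative integers")
    never <- N - rowSums(R4)
    if (any(never < 0)) {
      i <- which(never < 0)[1L]
      stop(what, ": group ", group_labels()[i],
           " has more reencounters than birds ringed (", rowSums(R4)[i],
           " > ", N[i], ")")
    }
    out <- cbind(R4, never)
    dimnames(out) <- list(group_labels(), c(area_labels(), "never"))
    out
  }
  check_counts <- function(R, what) {
    if (nrow(R) != n_groups()) stop(what, " must have 8 rows")
    if (any(is.na(R))) stop(what, " contains NA")
    if (any(R < 0) || any(R != round(R))) {
      idx <- which(R < 0 | R != round(R), arr.ind = TRUE)[1L, ]
      stop(what, ": entry [", idx[1L], ",", idx[2L],
           "] is not a nonnegative integer")
    }
  }
  R_ad_known <- pad(R_ad_known, N_ad, "R_ad_known")
  R_juv_known <- pad(R_juv_known, N_juv, "R_juv_known")
  R_ad_unknown <- as.matrix(R_ad_unknown)
  R_juv_unknown <- as.matrix(R_juv_unknown)
  check_counts(R_ad_unknown, "R_ad_unknown")
  check_counts(R_juv_unknown, "R_juv_unknown")
  if (ncol(R_ad_unknown) != 4L || ncol(R_juv_unknown) != 4L) {
    stop("unknown-total matrices must have 4 columns")
  }
  dimnames(R_ad_unknown) <- dimnames(R_juv_unknown) <-
    list(group_labels(), area_labels())
  structure(list(
    R_ad_known = R_ad_known, R_juv_known = R_juv_known,
    N_ad = stats::setNames(rowSums(R_ad_known), group_labels()),
    N_juv = stats::setNames(rowSums(R_juv_known), group_labels()),
    R_ad_unknown = R_ad_unknown, R_juv_unknown = R_juv_unknown,
    zero_unknown_rows = list(ad = rowSums(R_ad_unknown) == 0,
                             juv = rowSums(R_juv_unknown) == 0)
  ), class = "reencounter_data")
}

#' @export
print.reencounter_data <- function(x, ...) {
  cat("Ring-reencounter data: 8 groups x 4 wintering areas\n")
  cat("  known totals:   ad", sum(x$N_ad), "ringed /", sum(x$R_ad_known[, 1:4]),
      "reencountered; juv", sum(x$N_juv), "/", sum(x$R_juv_known[, 1:4]), "\n")
  cat("  unknown totals: ad", sum(x$R_ad_unknown), "reencounters; juv",
      sum(x$R_juv_unknown), "\n")
  invisible(x)
}

#' Tabulate grouped, area-assigned reencounter records into count matrices
#'
#' Each bird is counted at most once (the model's reencounter probability is
#' the probability of being reencountered at least once), so duplicate
#' `ring_id`s are collapsed to their first occurrence.
#'
#' @param records Data frame with columns `ring_id`, `group`, `area`,
#'   `age_class` (`"ad"`/`"juv"`), and logical `known` saying whether the
#'   number ringed is known for that bird's group/period.
#' @param n_ringed Data frame with columns `group`, `age_class`, `n_ringed`:
#'   the numbers ringed for the known-total strata (groups absent default
#'   to 0, in which case they must have no known-total reencounters).
#' @return A [reencounter_data()] object.
#' @export
build_reencounter_matrices <- function(records, n_ringed) {
  need <- c("ring_id", "group", "area", "age_class", "known")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  records <- records[!duplicated(records$ring_id), , drop = FALSE]
  if (!all(records$group %in% group_labels())) stop("unknown group label")
  if (!all(records$area %in% area_labels())) stop("unknown area label")
  if (!all(records$age_class %in% c("ad", "juv"))) stop("age_class must be ad/juv")

  tab <- function(df) {
    m <- matrix(0L, n_groups(), n_areas(),
                dimnames = list(group_labels(), area_labels()))
    if (nrow(df)) {
      t0 <- table(factor(df$group, group_labels()), factor(df$area, area_labels()))
      m[] <- as.integer(t0)
    }
    m
  }
  getN <- function(age) {
    N <- stats::setNames(numeric(n_groups()), group_labels())
    sel <- n_ringed$age_class == age
    N[n_ringed$group[sel]] <- n_ringed$n_ringed[sel]
    N
  }
  reencounter_data(
    R_ad_known = tab(records[records$known & records$age_class == "ad", ]),
    N_ad = getN("ad"),
    R_juv_known = tab(records[records$known & records$age_class == "juv", ]),
    N_juv = getN("juv"),
    R_ad_unknown = tab(records[!records$known & records$age_class == "ad", ]),
    R_juv_unknown = tab(records[!records$known & records$age_class == "juv", ])
  )
}

# ---- IsotopeData ------------------------------------------------------------

#' Construct per-individual stable-isotope data
#'
#' Stores the raw (d13C, d15N) feather values in per-mil and a z-scored
#' copy; the likelihood operates on the standardized scale.  When
#' `constants` is supplied (e.g. to place new data on the scale of a fitted
#' model) those means/sds are used instead of the data's own.
#'
#' @param values n x 2 numeric matrix (columns d13C, d15N).
#' @param pop Length-n population assignment: labels from
#'   [population_labels()] or integers 1..3.
#' @param constants Optional list with numeric length-2 `mean` and `sd`.
#' @return An object of class `isotope_data`.
#' @export
isotope_data <- function(values, pop, constants = NULL) {
  values <- as.matrix(values)
  if (nrow(values) == 0L) stop("no rows in isotope data")
  if (ncol(values) != 2L) stop("isotope values must have 2 columns (d13C, d15N)")
  if (any(is.na(values))) stop("NA in isotope values")
  dimnames(values) <- list(NULL, c("d13C", "d15N"))
  if (is.character(pop) || is.factor(pop)) {
    pop <- match(as.character(pop), population_labels())
  }
  pop <- as.integer(pop)
  if (length(pop) != nrow(values) || any(is.na(pop)) ||
      any(pop < 1L | pop > n_pops())) {
    stop("pop must map each row to one of the 3 breeding populations")
  }
  if (is.null(constants)) {
    constants <- list(mean = colMeans(values),
                      sd = apply(values, 2, stats::sd))
    if (any(constants$sd == 0 | is.na(constants$sd))) {
      stop("cannot standardize: zero or undefined column sd")
    }
  }
  std <- sweep(sweep(values, 2, constants$mean), 2, constants$sd, "/")
  structure(list(values = values, standardized = std, pop = pop,
                 standardization_constants = constants),
            class = "isotope_data")
}

#' @export
print.isotope_data <- function(x, ...) {
  cat("Isotope data:", nrow(x$values), "individuals;",
      paste(population_labels(), tabulate(x$pop, 3), collapse = ", "), "\n")
  invisible(x)
}

# ---- ParasiteData -----------------------------------------------------------

#' Construct parasite infection count tables
#'
#' Counts of infected (`G`) and sampled (`H`) blood samples per
#' haemosporidian lineage, for the four wintering areas (`nb`, any host
#' species) and the three breeding populations (`b`, the study species).
#'
#' @param G_nb,H_nb 4x5 matrices (areas x lineages).
#' @param G_b,H_b 3x5 matrices (populations x lineages).
#' @param lineages Five lineage names (defaults to the study's).
#' @return An object of class `parasite_data`.
#' @export
parasite_data <- function(G_nb, H_nb, G_b, H_b, lineages = lineage_labels()) {
  if (length(lineages) != n_lineages()) stop("exactly 5 lineages required")
  chk <- function(G, H, nr, rn, what) {
    G <- as.matrix(G); H <- as.matrix(H)
    if (!all(dim(G) == c(nr, n_lineages())) || !all(dim(H) == c(nr, n_lineages()))) {
      stop(what, " matrices must be ", nr, "x", n_lineages())
    }
    for (M in list(G, H)) {
      if (any(is.na(M)) || any(M < 0) || any(M != round(M))) {
        idx <- which(is.na(M) | M < 0 | M != round(M), arr.ind = TRUE)[1L, ]
        stop(what, ": entry [", idx[1L], ",", idx[2L],
             "] is not a nonnegative integer")
      }
    }
    if (any(G > H)) {
      idx <- which(G > H, arr.ind = TRUE)[1L, ]
      stop(what, ": infected exceeds sampled at [", rn[idx[1L]], ", ",
           lineages[idx[2L]], "]")
    }
    dimnames(G) <- dimnames(H) <- list(rn, lineages)
    list(G = G, H = H)
  }
  nb <- chk(G_nb, H_nb, n_areas(), area_labels(), "wintering (nb)")
  b <- chk(G_b, H_b, n_pops(), population_labels(), "breeding (b)")
  structure(list(G_nb = nb$G, H_nb = nb$H, G_b = b$G, H_b = b$H,
                 lineage_names = lineages),
            class = "parasite_data")
}

#' @export
print.parasite_data <- function(x, ...) {
  cat("Parasite data: 5 lineages;", sum(x$H_nb), "wintering-area samples (",
      sum(x$G_nb), "infected ),", sum(x$H_b), "breeding samples (",
      sum(x$G_b), "infected )\n")
  invisible(x)
}

# ---- CSV round trips --------------------------------------------------------

#' Read and write the package's CSV table formats
#'
#' `reencounters_known.csv` has columns `group`, `area_Western`,
#' `area_Central`, `area_Eastern`, `area_Southern`, `n_ringed`, `age_class`;
#' the unknown-totals file drops `n_ringed`.  `isotopes.csv` has
#' `individual_id`, `population`, `d13C`, `d15N`.  The parasite files have
#' `area_or_population`, `lineage`, `n_infected`, `n_sampled`.  Writing then
#' reading reproduces the object exactly.
#'
#' @param x Object to write.
#' @param known_path,unknown_path,path,nb_path,b_path File paths.
#' @return Readers return the reconstructed object; writers return the
#'   path(s) invisibly.
#' @name csv_io
NULL

#' @rdname csv_io
#' @export
write_reencounters <- function(x, known_path, unknown_path) {
  stopifnot(inherits(x, "reencounter_data"))
  area_cols <- paste0("area_", area_labels())
  mk <- function(R, N, age) {
    df <- data.frame(group = group_labels(), R[, 1:4, drop = FALSE],
                     check.names = FALSE, row.names = NULL)
    names(df)[2:5] <- area_cols
    if (!is.null(N)) df$n_ringed <- as.integer(N)
    df$age_class <- age
    df
  }
  known <- rbind(mk(x$R_ad_known, x$N_ad, "ad"), mk(x$R_juv_known, x$N_juv, "juv"))
  unknown <- rbind(mk(x$R_ad_unknown, NULL, "ad"), mk(x$R_juv_unknown, NULL, "juv"))
  utils::write.csv(known, known_path, row.names = FALSE)
  utils::write.csv(unknown, unknown_path, row.names = FALSE)
  invisible(c(known_path, unknown_path))
}

#' @rdname csv_io
#' @export
read_reencounters <- function(known_path, unknown_path) {
  area_cols <- paste0("area_", area_labels())
  rd <- function(path, need_n) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("group", area_cols, if (need_n) "n_ringed", "age_class")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop(path, ": missing columns ", paste(miss, collapse = ", "))
    for (col in c(area_cols, if (need_n) "n_ringed")) {
      v <- df[[col]]
      if (any(is.na(v)) || any(v < 0) || any(v != round(v))) {
        stop(path, ": column ", col, " row ",
             which(is.na(v) | v < 0 | v != round(v))[1L],
             " is not a nonnegative integer")
      }
    }
    df
  }
  pick <- function(df, age, cols) {
    sub <- df[df$age_class == age, , drop = FALSE]
    sub <- sub[match(group_labels(), sub$group), , drop = FALSE]
    if (anyNA(sub$group)) stop("known/unknown CSV must contain all 8 groups per age class")
    as.matrix(sub[, cols, drop = FALSE])
  }
  known <- rd(known_path, TRUE)
  unknown <- rd(unknown_path, FALSE)
  reencounter_data(
    R_ad_known = pick(known, "ad", area_cols),
    N_ad = pick(known, "ad", "n_ringed")[, 1],
    R_juv_known = pick(known, "juv", area_cols),
    N_juv = pick(known, "juv", "n_ringed")[, 1],
    R_ad_unknown = pick(unknown, "ad", area_cols),
    R_juv_unknown = pick(unknown, "juv", area_cols)
  )
}

#' @rdname csv_io
#' @export
write_isotopes <- function(x, path) {
  stopifnot(inherits(x, "isotope_data"))
  df <- data.frame(individual_id = seq_len(nrow(x$values)),
                   population = population_labels()[x$pop],
                   d13C = x$values[, 1], d15N = x$values[, 2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname csv_io
#' @export
read_isotopes <- function(path, constants = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "population", "d13C", "d15N")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(path, ": missing columns ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop(path, ": no rows")
  isotope_data(cbind(df$d13C, df$d15N), df$population, constants = constants)
}

#' @rdname csv_io
#' @export
write_parasites <- function(x, nb_path, b_path) {
  stopifnot(inherits(x, "parasite_data"))
  melt <- function(G, H) {
    data.frame(area_or_population = rep(rownames(G), times = ncol(G)),
               lineage = rep(colnames(G), each = nrow(G)),
               n_infected = as.integer(G), n_sampled = as.integer(H))
  }
  utils::write.csv(melt(x$G_nb, x$H_nb), nb_path, row.names = FALSE)
  utils::write.csv(melt(x$G_b, x$H_b), b_path, row.names = FALSE)
  invisible(c(nb_path, b_path))
}

#' @rdname csv_io
#' @export
read_parasites <- function(nb_path, b_path) {
  rd <- function(path, rows) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("area_or_population", "lineage", "n_infected", "n_sampled")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop(path, ": missing columns ", paste(miss, collapse = ", "))
    lineages <- unique(df$lineage)
    if (length(lineages) != n_lineages()) stop(path, ": expected 5 lineages")
    G <- matrix(NA_real_, length(rows), n_lineages(), dimnames = list(rows, lineages))
    H <- G
    for (r in seq_len(nrow(df))) {
      i <- match(df$area_or_population[r], rows)
      j <- match(df$lineage[r], lineages)
      if (is.na(i)) stop(path, ": unknown area/population '",
                         df$area_or_population[r], "' at row ", r)
      G[i, j] <- df$n_infected[r]
      H[i, j] <- df$n_sampled[r]
    }
    if (any(is.na(G))) stop(path, ": incomplete table")
    list(G = G, H = H, lineages = lineages)
  }
  nb <- rd(nb_path, area_labels())
  b <- rd(b_path, population_labels())
  if (!identical(nb$lineages, b$lineages)) {
    stop("lineage sets differ between wintering and breeding files")
  }
  parasite_data(nb$G, nb$H, b$G, b$H, lineages = nb$lineages)
}

#' Bundle the three data sources
#'
#' @param rings A [reencounter_data()] or `NULL`.
#' @param isotopes An [isotope_data()] or `NULL`.
#' @param parasites A [parasite_data()] or `NULL`.
#' @return A list of class `mc_bundle`.
#' @export
mc_bundle <- function(rings = NULL, isotopes = NULL, parasites = NULL) {
  if (!is.null(rings)) stopifnot(inherits(rings, "reencounter_data"))
  if (!is.null(isotopes)) stopifnot(inherits(isotopes, "isotope_data"))
  if (!is.null(parasites)) stopifnot(inherits(parasites, "parasite_data"))
  structure(list(rings = rings, isotopes = isotopes, parasites = parasites),
            class = "mc_bundle")
}
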