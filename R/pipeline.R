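#' Pipeline run configuration
#'
#' @param generator An `eui_generator_config` used to synthesize microdata,
#'   or `NULL` when `input` is given.
#' @param input Path to a microdata CSV (ignored when `generator` is set).
#' @param schema Schema used to validate `input`.
#' @param ecp_grid ECP threshold grid (values in `[0,1]`, strictly
#'   increasing).
#' @param bootstrap_n Number of bootstrap replicates (0 disables the
#'   stability stage).
#' @param bootstrap_max_records Cap on the number of records scored in the
#'   bootstrap stage (sampled deterministically from the seed).
#' @param adjust_ecp0 Threshold at which the EUI counts entering the
#'   population-level adjustment are formed (0 = every EUI gets its argmax
#'   cause, the canonical choice since the adjustment is meant to cover all
#'   EUIs).
#' @param comparators Run the proportional-redistribution and
#'   fuzzy-sharing comparators.
#' @param sexes Which sex strata to run (`"male"`, `"female"`).
#' @return Object of class `eui_run_config`.
#' @export
run_config <- function(generator = NULL, input = NULL,
                       schema = default_schema(),
                       ecp_grid = DEFAULT_ECP_GRID,
                       bootstrap_n = 250L,
                       bootstrap_max_records = 20000L,
                       adjust_ecp0 = 0,
                       comparators = TRUE,
                       sexes = c("male", "female")) {
  if (is.null(generator) && is.null(input)) {
    stop("provide either a generator config or an input CSV path")
  }
  if (any(ecp_grid < 0) || any(ecp_grid > 1) || is.unsorted(ecp_grid,
                                                           strictly = TRUE)) {
    stop("ecp_grid must be strictly increasing values in [0, 1]")
  }
  if (bootstrap_n < 0) stop("bootstrap_n must be nonnegative")
  structure(
    list(generator = generator, input = input, schema = schema,
         ecp_grid = ecp_grid, bootstrap_n = as.integer(bootstrap_n),
         bootstrap_max_records = as.integer(bootstrap_max_records),
         adjust_ecp0 = adjust_ecp0, comparators = comparators,
         sexes = sexes),
    class = "eui_run_config"
  )
}

write_table <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

class_matrix_table <- function(cm, per_1000 = TRUE) {
  d <- cm$d
  scale <- if (per_1000 && sum(d) > 0) 1000 / sum(d) else 1
  ag <- agreement_share(cm)
  data.frame(
    predicted = rownames(d),
    round(d * scale, 1),
    total = round(rowSums(d) * scale, 1),
    share_agreement = round(ifelse(cm$D_P > 0, diag(d) / cm$D_P, NA), 2),
    overall_agreement = round(ag$overall, 3),
    ecp0 = cm$ecp0, unclassified = cm$unclassified,
    stringsAsFactors = FALSE
  )
}

#' Run the full reclassification pipeline
#'
#' Orchestrates generate/ingest, per-sex model fitting, training-set
#' evaluation over the ECP threshold grid, EUI reclassification, the
#' population-level adjustment, comparator redistributions, rate tables,
#' and the bootstrap stability report. All artifacts are CSV/JSON files
#' under `out`; runs with the same config and seed are byte-identical.
#'
#' @param config An `eui_run_config`.
#' @param seed Integer master seed for every random stage.
#' @param out Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`models`,
#'   `evaluation`, `eui`, `rates`, `bootstrap`, `manifest`).
#' @export
run_pipeline <- function(config, seed = 1L, out = tempfile("eui_run_")) {
  stopifnot(inherits(config, "eui_run_config"))
  seed <- as.integer(seed)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  schema <- if (!is.null(config$generator)) config$generator$schema
            else config$schema

  # ---- stage: ingest / generate -----------------------------------------
  if (!is.null(config$generator)) {
    gen <- generate_microdata(config$generator, seed = seed)
    records <- gen$records
    population <- gen$population
    write_microdata(records, file.path(out, "microdata.csv"))
    utils::write.csv(gen$truth, file.path(out, "ground_truth.csv"),
                     row.names = FALSE)
  } else {
    records <- read_microdata(config$input, schema)
    population <- NULL
  }
  message("pipeline: ", nrow(records), " records ingested (",
          sum(records$cause_class == "EUI"), " EUI)")

  known <- records[records$cause_class %in% CAUSE_LEVELS, , drop = FALSE]
  euis <- records[records$cause_class == "EUI", , drop = FALSE]

  models <- list(); evaluation <- list(); eui_out <- list()
  boot <- list()
  eui_contrib_rows <- list()

  for (sx in config$sexes) {
    k_sx <- known[known$sex == sx, , drop = FALSE]
    e_sx <- euis[euis$sex == sx, , drop = FALSE]
    message("pipeline[", sx, "]: fitting on ", nrow(k_sx),
            " known-cause records")
    enc <- build_encoding(k_sx, schema)
    model <- fit_mlogit(k_sx, enc)
    models[[sx]] <- model
    write_model(model, file.path(out, paste0("model_", sx, ".json")))

    # ---- training-set evaluation over the grid --------------------------
    ecp_train <- predict_ecp(model, k_sx)
    eval_rows <- list(); summary_rows <- list()
    cms <- list()
    for (e0 in config$ecp_grid) {
      cm <- build_class_matrix(model, k_sx, e0, ecp = ecp_train)
      cms[[as.character(e0)]] <- cm
      eval_rows[[as.character(e0)]] <- class_matrix_table(cm)
      summary_rows[[as.character(e0)]] <- data.frame(
        sex = sx, ecp0 = e0,
        t(round(relative_error(cm), 4)),
        unclassified_share = round(cm$unclassified / cm$n_scored, 4),
        stringsAsFactors = FALSE
      )
    }
    evaluation[[sx]] <- list(class_matrices = cms,
                             summary = do.call(rbind, summary_rows))
    write_table(do.call(rbind, eval_rows), out,
                paste0("evaluation_", sx, ".csv"))
    write_table(evaluation[[sx]]$summary, out,
                paste0("prediction_errors_", sx, ".csv"))

    # ---- EUI reclassification -------------------------------------------
    if (nrow(e_sx) == 0L) {
      message("pipeline[", sx, "]: no EUI records; adjustment skipped")
      eui_out[[sx]] <- NULL
    } else {
      ecp_eui <- predict_ecp(model, e_sx)
      dist_row <- function(variant, shares, unclassified) {
        data.frame(sex = sx, variant = variant,
                   NTA = round(shares[[1]], 1), SUI = round(shares[[2]], 1),
                   HOM = round(shares[[3]], 1),
                   unclassified = round(unclassified, 1),
                   stringsAsFactors = FALSE)
      }
      dist_rows <- list()
      for (e0 in config$ecp_grid) {
        rc <- reclassify_euis(model, e_sx, e0, ecp = ecp_eui)
        dist_rows[[as.character(e0)]] <- dist_row(
          sprintf("ECP>=%.2f", e0), 1000 * rc$U / rc$n_eui,
          1000 * rc$unclassified / rc$n_eui)
      }
      cm_adj <- evaluation[[sx]]$class_matrices[[
        as.character(config$adjust_ecp0)]]
      if (is.null(cm_adj)) {
        cm_adj <- build_class_matrix(model, k_sx, config$adjust_ecp0,
                                     ecp = ecp_train)
      }
      mm <- build_misclass_matrix(cm_adj)
      rc0 <- reclassify_euis(model, e_sx, config$adjust_ecp0, ecp = ecp_eui)
      U_adj <- population_adjust(mm, rc0$U)
      dist_rows[["adjusted"]] <- dist_row("population_adjusted",
                                          1000 * U_adj / rc0$n_eui, 0)
      if (isTRUE(config$comparators)) {
        strata <- stats::aggregate(
          cbind(NTA = cause_class == "NTA", SUI = cause_class == "SUI",
                HOM = cause_class == "HOM") ~ sex + age_group,
          data = known[known$sex == sx, ], FUN = sum)
        eui_strata <- stats::aggregate(
          list(eui = rep(1L, nrow(e_sx))),
          by = list(sex = e_sx$sex, age_group = e_sx$age_group), FUN = sum)
        strata <- merge(strata, eui_strata, all = TRUE)
        strata$eui[is.na(strata$eui)] <- 0
        for (cl in CAUSE_LEVELS) strata[[cl]][is.na(strata[[cl]])] <- 0
        pr <- proportional_redistribution(strata)
        pr_tot <- colSums(pr[paste0(CAUSE_LEVELS, "_redist")])
        dist_rows[["proportional"]] <- dist_row(
          "proportional_redistribution", 1000 * pr_tot / sum(pr_tot), 0)
        fz <- fuzzy_sharing_redistribution(ecp_eui)
        dist_rows[["fuzzy"]] <- dist_row("fuzzy_sharing",
                                         1000 * fz / sum(fz), 0)
      }
      dist <- do.call(rbind, dist_rows)
      write_table(dist, out, paste0("eui_distribution_", sx, ".csv"))
      write_table(data.frame(predicted = CAUSE_LEVELS, round(mm$P, 4)),
                  out, paste0("misclass_matrix_", sx, ".csv"))
      eui_out[[sx]] <- list(distribution = dist, misclass = mm,
                            U = rc0$U, U_adj = U_adj, n_eui = rc0$n_eui)

      # record-level realization of the adjustment for age-specific rates:
      # an EUI predicted as cause i contributes P_ij of a death to cause j
      pred0 <- assign_cause(ecp_eui, config$adjust_ecp0)
      ok <- !is.na(pred0)
      if (any(ok)) {
        w_mat <- mm$P[match(pred0[ok], CAUSE_LEVELS), , drop = FALSE]
        for (j in seq_along(CAUSE_LEVELS)) {
          eui_contrib_rows[[paste(sx, j)]] <- data.frame(
            sex = sx, year = as.character(e_sx$year[ok]),
            cause = CAUSE_LEVELS[j],
            age_group = as.character(e_sx$age_group[ok]),
            deaths = w_mat[, j], stringsAsFactors = FALSE)
        }
      }
    }

    # ---- bootstrap stability --------------------------------------------
    if (config$bootstrap_n > 0L) {
      target <- if (nrow(e_sx)) e_sx else k_sx
      if (nrow(target) > config$bootstrap_max_records) {
        set.seed(seed + 7L)
        target <- target[sample.int(nrow(target),
                                    config$bootstrap_max_records), ]
      }
      boot[[sx]] <- stability_analysis(model, target,
                                       n_replicates = config$bootstrap_n,
                                       seed = seed + 13L)
      write_table(data.frame(max_ecp = round(boot[[sx]]$max_ecp, 6),
                             agreement = boot[[sx]]$agreement),
                  out, paste0("bootstrap_", sx, ".csv"))
    }
  }

  # ---- rates -------------------------------------------------------------
  rates_tab <- NULL
  if (!is.null(population)) {
    official <- stats::aggregate(
      list(deaths = rep(1L, nrow(known))),
      by = list(sex = as.character(known$sex),
                year = as.character(known$year),
                cause = as.character(known$cause_class),
                age_group = as.character(known$age_group)),
      FUN = sum)
    eui_contrib <- if (length(eui_contrib_rows)) {
      do.call(rbind, eui_contrib_rows)
    } else official[0L, ]
    rates_tab <- adjusted_series(official, eui_contrib, population)
    rates_csv <- rates_tab
    rates_csv[c("official_sdr", "eui_sdr", "adjusted_sdr")] <-
      round(rates_csv[c("official_sdr", "eui_sdr", "adjusted_sdr")], 2)
    rates_csv$eui_share <- round(rates_csv$eui_share, 3)
    write_table(rates_csv, out, "rates.csv")
  }

  # ---- manifest ----------------------------------------------------------
  cfg_file <- file.path(out, "config_echo.json")
  writeLines(jsonlite::toJSON(
    list(ecp_grid = config$ecp_grid, bootstrap_n = config$bootstrap_n,
         adjust_ecp0 = config$adjust_ecp0, sexes = config$sexes,
         generator = if (!is.null(config$generator))
           config$generator[c("n_records", "cause_mix")],
         masking = if (!is.null(config$generator))
           config$generator$masking),
    digits = NA, auto_unbox = TRUE), cfg_file)
  manifest <- list(
    package = "euireclass",
    version = as.character(utils::packageVersion("euireclass")),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    n_records = nrow(records),
    n_eui = sum(records$cause_class == "EUI"),
    artifacts = sort(list.files(out))
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out, "manifest.json"))

  invisible(list(models = models, evaluation = evaluation, eui = eui_out,
                 rates = rates_tab, bootstrap = boot, manifest = manifest,
                 out = out))
}

#' Command-line entry point
#'
#' Minimal flag parser driving [run_pipeline()] with the Russia-like
#' synthetic generator; see `exec/eui-reclass` for the installed script.
#' Flags: `--n INT` records, `--seed INT`, `--out DIR`,
#' `--ecp0-grid v1,v2,...`, `--sex male|female|both`,
#' `--bootstrap-n INT`, `--masking uniform|covariate|hidden_homicide`,
#' `--input PATH` (use a microdata CSV instead of the generator).
#'
#' @param args Character vector of command-line arguments.
#' @return The [run_pipeline()] result, invisibly.
#' @export
eui_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  opt <- list(n = 20000L, seed = 1L, out = "eui_run",
              `ecp0-grid` = DEFAULT_ECP_GRID, sex = "both",
              `bootstrap-n` = 250L, masking = "default", input = NULL)
  i <- 1L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!(key %in% names(opt))) stop("unknown flag: ", args[i])
    val <- args[i + 1L]
    opt[[key]] <- switch(key,
      n = , seed = , `bootstrap-n` = as.integer(val),
      `ecp0-grid` = as.numeric(strsplit(val, ",")[[1L]]),
      val)
    i <- i + 2L
  }
  sexes <- if (opt$sex == "both") c("male", "female") else opt$sex
  generator <- NULL
  if (is.null(opt$input)) {
    masking <- switch(opt$masking,
      default = masking_uniform(c(0.125, 0.115, 0.30)),
      uniform = masking_uniform(0.15),
      covariate = masking_covariate(c(0.125, 0.115, 0.30)),
      hidden_homicide = masking_hidden_homicide(),
      stop("unknown masking scenario: ", opt$masking))
    generator <- default_russia_like_config(n_records = opt$n,
                                            masking = masking,
                                            seed = opt$seed)
  }
  cfg <- run_config(generator = generator, input = opt$input,
                    ecp_grid = opt$`ecp0-grid`,
                    bootstrap_n = opt$`bootstrap-n`, sexes = sexes)
  res <- run_pipeline(cfg, seed = opt$seed, out = opt$out)
  message("pipeline complete; artifacts in ", res$out)
  invisible(res)
}
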