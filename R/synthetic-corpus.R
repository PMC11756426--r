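#' Generator configuration for the synthetic obstetric-note corpus
#'
#' The study's EHR corpus is not shareable, so every pipeline stage is
#' exercised on a synthetic stand-in corpus that emulates its structure:
#' seven narrative note types with structured sections and a free-text
#' body, planted 1--3-sentence exemplars of the six language categories
#' at configurable prevalence, paraphrased twins of gold exemplars
#' planted only in unannotated notes (so retrieval has something to
#' find), and abbreviation / HTML-entity / letter-case noise.
#'
#' The default prevalences mirror the imbalance of the study's initial
#' gold standard (roughly 41/15/10/7/5/21 percent across marginalized,
#' difficult patient, power/privilege, unilateral/authoritarian,
#' questioning credibility and positive/preferred), scaled so 600 notes
#' carry about 150 gold exemplars.
#'
#' @param n_notes Number of notes.
#' @param note_type_mix Named probabilities over [note_types()].
#' @param category_prevalence Expected exemplars per 100 notes, named by
#'   category.
#' @param paraphrase_rate Probability that a gold exemplar also gets a
#'   paraphrased twin planted in an unannotated note.
#' @param width_probs Probabilities of exemplar widths 1, 2, 3 sentences.
#' @param noise Rates `c(abbreviation, entity, case_jitter)` applied to
#'   neutral filler sentences.
#' @param annotated_fraction Fraction of notes marked as human-annotated.
#' @param seed Generation seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(
    n_notes = 600L,
    note_type_mix = stats::setNames(rep(1 / 7, 7), note_types()),
    category_prevalence = c(marginalized = 10.3, difficult_patient = 3.8,
                            power_privilege = 2.4,
                            unilateral_authoritarian = 1.8,
                            questioning_credibility = 1.3,
                            positive_preferred = 5.3),
    paraphrase_rate = 0.5,
    width_probs = c(0.6, 0.3, 0.1),
    noise = c(abbreviation = 0.2, entity = 0.1, case_jitter = 0.1),
    annotated_fraction = 0.4,
    seed = 1L) {
  stopifnot(n_notes >= 1, all(category_prevalence >= 0),
            paraphrase_rate >= 0, paraphrase_rate <= 1,
            all(noise >= 0), all(noise <= 1),
            annotated_fraction >= 0, annotated_fraction <= 1,
            length(width_probs) == 3, all(width_probs >= 0))
  check_categories(names(category_prevalence), allow_none = FALSE)
  structure(list(n_notes = as.integer(n_notes),
                 note_type_mix = note_type_mix,
                 category_prevalence = category_prevalence,
                 paraphrase_rate = paraphrase_rate,
                 width_probs = width_probs / sum(width_probs),
                 noise = noise,
                 annotated_fraction = annotated_fraction,
                 seed = seed),
            class = "generator_config")
}

#' Template phrase bank
#'
#' At least ten templates per substantive category, written in the voice
#' of the study's category exemplars (e.g. "poor effort with pushing",
#' "reports nurturing marriage", "unsure if patient telling the truth").
#' Templates contain alternation groups `(a|b)` and numeric slots
#' `{num}`; rendering picks one alternative per group, and a paraphrase
#' re-renders the same template with some alternatives switched, which
#' keeps high character-level overlap while changing the surface form.
#'
#' @return Tibble with columns `category`, `template_id`, `template`.
#' @export
phrase_bank <- function() {
  bank <- list(
    marginalized = c(
      "patient is a {num} yo (unmarried|single) (unemployed|not working) female.",
      "she (does not use|denies using) drugs or smoke but drinks {num}x week.",
      "(toxic|poor) habits (noted|documented) in chart.",
      "patient (denies|refuses to discuss) illicit (drug|substance) use.",
      "(teen|adolescent) mother with (limited|poor) support at home.",
      "late registrant with (no|minimal) prenatal care this pregnancy.",
      "financially supports self, (lives alone|no partner in home).",
      "history of (incarceration|jail time) (noted|reported) during intake.",
      "patient presents as (disheveled|unkempt) and (poorly groomed|untidy).",
      "obesity (noted|documented), bmi {num}.",
      "housing (unstable|insecure), currently (staying in a shelter|between residences)."),
    difficult_patient = c(
      "(poor|minimal) effort with pushing (noted|observed).",
      "patient (complaining|complains) of (lightheadedness|dizziness) (again|repeatedly).",
      "(noncompliant|nonadherent) with (bed rest|medication) (instructions|recommendations).",
      "patient (refused|declined repeatedly) (vital signs|assessment) (this shift|overnight).",
      "fob is {num} yo unemployed and not as (involved|engaged) as he should be.",
      "patient (demanding|insistent on) (pain medication|early discharge) (despite|against) advice.",
      "(argumentative|hostile) with (nursing staff|the care team) (this morning|overnight).",
      "patient (refuses|will not allow) (lab draws|blood work) (again|at this time).",
      "(uncooperative|combative) during (exam|assessment) despite (repeated|multiple) explanations.",
      "call bell used (constantly|excessively) for (minor|non urgent) requests."),
    power_privilege = c(
      "reports (nurturing|supportive) marriage.",
      "private pt of mine at {num} wks with (multiple|several) episodes of emesis.",
      "husband is a (neurosurgeon|physician|attorney).",
      "patient is a (well educated|accomplished) (professional|executive).",
      "(well spoken|articulate) and (pleasant|gracious) (family|couple).",
      "(strong|excellent) family support, (parents|in laws) (at bedside|readily available).",
      "patient works as a (professor|engineer|consultant) (locally|downtown).",
      "(well groomed|impeccably dressed) and in no (acute|apparent) distress.",
      "(lovely|delightful) (couple|family), (very|highly) engaged in care.",
      "(stable|comfortable) (home|financial) situation (reported|noted)."),
    unilateral_authoritarian = c(
      "(intolerant of|did not tolerate) vaginal exam.",
      "sw has advised pt that if (yelling|shouting) in room continues acs will (need to be|be) contacted.",
      "patient was (told|instructed) she (must|needs to) remain in bed.",
      "(allowed|permitted) patient to (ambulate|shower) (briefly|once).",
      "patient (must|is expected to) (comply with|follow) unit (policy|rules).",
      "made it clear to patient that (refusal|noncompliance) is not an option.",
      "patient (needs|requires) (strict|close) supervision with infant care.",
      "(insisted|insists) patient (accept|agree to) the (plan|intervention) as written.",
      "patient (warned|cautioned) that security will be (called|notified) if behavior continues.",
      "(denied|refused) patient request to (delay|defer) the (exam|procedure)."),
    questioning_credibility = c(
      "unsure if patient (telling|is telling) the truth.",
      "pt denied any other dv incidents and was adamant that the relationship was healthy.",
      "patient (claims|alleges) (severe|constant) pain but (appears|seems) comfortable.",
      "(doubt|question) the (accuracy|reliability) of her (history|report).",
      "patient (states|reports) she took her medications though (pharmacy records|the record) (suggest|show) otherwise.",
      "(supposedly|allegedly) (fell|slipped) at home (last night|yesterday).",
      "reports (daily|frequent) palpitations but able to walk several city blocks without issue.",
      "her (story|account) (keeps changing|is inconsistent) (between|across) interviews.",
      "patient (insists|maintains) she (has not|never) smoked though odor (suggests|indicates) otherwise.",
      "(exaggerating|overstating) symptoms (per|according to) (night shift|previous) notes."),
    positive_preferred = c(
      "patient desires epidural prior to starting induction.",
      "patient (declines|declined) epidural at this time, trying to deliver without analgesia.",
      "on exam patient endorses numbness across (bilateral|both) buttocks.",
      "patient (prefers|wishes) to (breastfeed|feed on demand) exclusively.",
      "patient (expresses|voices) a preference for (skin to skin|rooming in) after delivery.",
      "amniocentesis was offered and the patient (declined|deferred) after discussion.",
      "patient (chooses|elects) to (ambulate|use the birthing ball) during early labor.",
      "patient (asks|requests) that her (partner|support person) remain at bedside.",
      "patient (describes|reports) her (pain|contractions) as (manageable|tolerable) at present.",
      "patient (declines|defers) (formula supplementation|pacifier use) for now."))
  dplyr::bind_rows(purrr::imap(bank, function(tpls, cat) {
    tibble::tibble(category = cat,
                   template_id = sprintf("%s_%02d", cat, seq_along(tpls)),
                   template = tpls)
  }))
}

# Neutral filler sentence templates: routine obstetric narrative with a
# vocabulary deliberately distinct from the category phrases.
filler_bank <- function() {
  c("vital signs (stable|within normal limits) (this shift|overnight).",
    "fundus (firm|midline) at (the umbilicus|one below umbilicus).",
    "lochia (moderate|scant) (rubra|serosa).",
    "fetal heart tones {num} with (moderate|minimal) variability.",
    "ambulating (in hallway|to bathroom) without (difficulty|assistance).",
    "tolerating (regular|clear) diet without nausea.",
    "incision (clean|dry) and (intact|well approximated).",
    "voiding (spontaneously|without difficulty).",
    "infant (latching well|feeding every three hours).",
    "iv site (patent|without redness).",
    "pain rated {num} of 10, (controlled|improving) with current regimen.",
    "plan to (continue routine postpartum care|reassess in the morning).",
    "membranes (intact|ruptured) at (admission|0600).",
    "cervical exam (deferred|unchanged) (this morning|at present).",
    "breath sounds clear (bilaterally|throughout).",
    "edema (trace|mild) in (lower extremities|ankles).",
    "patient resting (comfortably|quietly) in bed.",
    "no (calf tenderness|headache|visual changes) reported.")
}

section_bank <- function() {
  list(c("Vitals:", "bp 118/72 hr 82 rr 16 temp 98.6"),
       c("Medications:", "prenatal vitamin; docusate prn"),
       c("Allergies:", "no known drug allergies"),
       c("Labs:", "hgb 11.2 plt 240"),
       c("Diet:", "regular"),
       c("Activity:", "ad lib"))
}

# Render a template: pick one alternative per (a|b|...) group and fill
# {num} slots. `prior` is a previous rendering whose slot values are
# reused and whose group choices are perturbed (paraphrase mode).
render_template <- function(template, prior = NULL) {
  m <- gregexpr("\\([^()]+\\)|\\{num\\}", template)[[1]]
  if (m[1] == -1) {
    return(list(text = template, choices = integer(), values = integer()))
  }
  tokens <- regmatches(template, gregexpr("\\([^()]+\\)|\\{num\\}",
                                          template))[[1]]
  choices <- integer(0)
  values <- integer(0)
  out <- template
  gi <- 0L
  vi <- 0L
  for (tok in tokens) {
    if (tok == "{num}") {
      vi <- vi + 1L
      val <- if (!is.null(prior) && vi <= length(prior$values)) {
        prior$values[vi]
      } else sample(15:44, 1)
      values <- c(values, val)
      out <- sub("{num}", val, out, fixed = TRUE)
    } else {
      gi <- gi + 1L
      alts <- strsplit(substr(tok, 2, nchar(tok) - 1), "|", fixed = TRUE)[[1]]
      ch <- if (!is.null(prior) && gi <= length(prior$choices)) {
        prev <- prior$choices[gi]
        if (length(alts) > 1 && stats::runif(1) < 0.5) {
          sample(setdiff(seq_along(alts), prev), 1)
        } else prev
      } else sample.int(length(alts), 1)
      choices <- c(choices, ch)
      out <- sub(tok, alts[ch], out, fixed = TRUE)
    }
  }
  list(text = out, choices = choices, values = values)
}

apply_noise <- function(sentence, noise) {
  if (stats::runif(1) < noise[["abbreviation"]]) {
    sentence <- sub("(?<![[:alnum:]])patient(?![[:alnum:]])", "pt.",
                    sentence, perl = TRUE)
  }
  if (stats::runif(1) < noise[["entity"]]) {
    words <- strsplit(sentence, " ")[[1]]
    # never wrap the final word: its period must stay sentence-terminal
    if (length(words) > 1) {
      i <- sample.int(length(words) - 1, 1)
      words[i] <- paste0("&quot;", words[i], "&quot;")
      sentence <- paste(words, collapse = " ")
    }
  }
  if (stats::runif(1) < noise[["case_jitter"]]) {
    words <- strsplit(sentence, " ")[[1]]
    i <- sample.int(length(words), 1)
    words[i] <- toupper(words[i])
    sentence <- paste(words, collapse = " ")
  }
  sentence
}

#' Generate a synthetic labeled corpus
#'
#' Produces a corpus of clinical notes, the gold annotated dataset of
#' planted exemplars (all in notes with `annotated_flag = TRUE`), and a
#' ground-truth span table covering both gold exemplars and their
#' paraphrased twins (planted only in unannotated notes). Offsets in the
#' truth table are 0-based end-exclusive character positions into each
#' note's `free_text`; sentence indices are 1-based over the note's
#' sentence list. Output is deterministic given the configuration.
#'
#' @param config A [generator_config()].
#' @return A list with `notes` (corpus tibble), `gold` (exemplar tibble)
#'   and `truth` (span tibble with columns `note_id`, `first_sentence`,
#'   `last_sentence`, `start`, `end`, `category`, `kind`
#'   (`"gold"`/`"paraphrase"`), `exemplar_id`).
#' @export
#' @examples
#' out <- generate_corpus(generator_config(n_notes = 30, seed = 7))
#' nrow(out$notes)
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_notes
  n_cat <- round_half_away(config$category_prevalence * n / 100)
  total_ex <- sum(n_cat)
  n_annot <- as.integer(round_half_away(config$annotated_fraction * n))
  if (total_ex > 0 && n_annot == 0) {
    stop("infeasible config: exemplars requested but no notes are marked ",
         "for annotation", call. = FALSE)
  }
  if (n_annot > 0 && total_ex > 5 * n_annot) {
    stop("infeasible config: ", total_ex, " exemplars cannot be planted in ",
         n_annot, " annotated notes (limit 5 per note)", call. = FALSE)
  }
  bank <- phrase_bank()
  fillers <- filler_bank()
  sections <- section_bank()

  with_seed(config$seed, {
    note_type <- sample(names(config$note_type_mix), n, replace = TRUE,
                        prob = config$note_type_mix)
    annot_ids <- sort(sample.int(n, n_annot))
    annotated_flag <- seq_len(n) %in% annot_ids

    base_sentences <- purrr::map(seq_len(n), function(i) {
      k <- sample(5:8, 1)
      vapply(sample(fillers, k, replace = (k > length(fillers))), function(tpl) {
        apply_noise(render_template(tpl)$text, config$noise)
      }, character(1))
    })
    structured <- purrr::map(seq_len(n), function(i) {
      picks <- sections[sample.int(length(sections), sample(2:3, 1))]
      tibble::tibble(header = vapply(picks, `[`, "", 1),
                     text = vapply(picks, `[`, "", 2))
    })

    # plan the gold exemplars
    plants <- list()
    gold_rows <- list()
    host_load <- stats::setNames(integer(length(annot_ids)),
                                 as.character(annot_ids))
    ex_i <- 0L
    for (cat in names(n_cat)) {
      tpl_rows <- which(bank$category == cat)
      for (j in seq_len(n_cat[[cat]])) {
        ex_i <- ex_i + 1L
        width <- sample(1:3, 1, prob = config$width_probs)
        picks <- sample(tpl_rows, width)
        renders <- purrr::map(picks, function(r) {
          c(list(template = bank$template[r]),
            render_template(bank$template[r]))
        })
        open <- names(host_load)[host_load < 5L]
        host <- as.integer(if (length(open) == 1) open else sample(open, 1))
        host_load[as.character(host)] <- host_load[as.character(host)] + 1L
        id <- sprintf("gold%05d", ex_i)
        plants[[length(plants) + 1]] <- list(
          note = host, kind = "gold", category = cat, id = id,
          sentences = vapply(renders, `[[`, "", "text"))
        gold_rows[[ex_i]] <- list(id = id, note = host, category = cat,
                                  width = width, renders = renders)
      }
    }

    # paraphrased twins in unannotated notes
    unannot <- setdiff(seq_len(n), annot_ids)
    for (g in gold_rows) {
      if (length(unannot) == 0) break
      if (stats::runif(1) < config$paraphrase_rate) {
        para <- vapply(g$renders, function(r) {
          render_template(r$template, prior = r)$text
        }, character(1))
        host <- if (length(unannot) == 1) unannot else sample(unannot, 1)
        plants[[length(plants) + 1]] <- list(
          note = host, kind = "paraphrase", category = g$category,
          id = g$id, sentences = para)
      }
    }

    # assemble notes: insert planted spans into the filler sentences
    spans <- list()
    sentences <- base_sentences
    for (p in plants) {
      s <- sentences[[p$note]]
      # never insert inside an already-planted span of the same note
      inside <- unlist(purrr::map(spans, function(sp) {
        if (sp$note == p$note && sp$last > sp$first) {
          sp$first:(sp$last - 1L)
        } else integer()
      }))
      cand <- setdiff(0:length(s), inside)
      pos <- if (length(cand) == 1) cand else sample(cand, 1)
      w <- length(p$sentences)
      sentences[[p$note]] <- append(s, p$sentences, after = pos)
      # shift earlier-recorded spans in the same note
      for (k in seq_along(spans)) {
        if (spans[[k]]$note == p$note && spans[[k]]$first > pos) {
          spans[[k]]$first <- spans[[k]]$first + w
          spans[[k]]$last <- spans[[k]]$last + w
        }
      }
      spans[[length(spans) + 1]] <- list(note = p$note, first = pos + 1L,
                                         last = pos + w, kind = p$kind,
                                         category = p$category, id = p$id)
    }

    note_id <- sprintf("note%05d", seq_len(n))
    free_text <- vapply(sentences, paste, character(1), collapse = " ")
    notes <- tibble::tibble(note_id = note_id, note_type = note_type,
                            structured_sections = structured,
                            free_text = free_text,
                            annotated_flag = annotated_flag)

    truth <- purrr::map(spans, function(sp) {
      s <- sentences[[sp$note]]
      lens <- nchar(s)
      # 0-based start: preceding sentences plus one joiner space each
      start <- if (sp$first == 1) 0L else
        sum(lens[seq_len(sp$first - 1)]) + (sp$first - 1L)
      end <- start + sum(lens[sp$first:sp$last]) + (sp$last - sp$first)
      tibble::tibble(note_id = note_id[sp$note], first_sentence = sp$first,
                     last_sentence = sp$last, start = as.integer(start),
                     end = as.integer(end), category = sp$category,
                     kind = sp$kind, exemplar_id = sp$id)
    })
    truth <- dplyr::bind_rows(truth)
    if (nrow(truth) == 0) {
      truth <- tibble::tibble(note_id = character(), first_sentence = integer(),
                              last_sentence = integer(), start = integer(),
                              end = integer(), category = character(),
                              kind = character(), exemplar_id = character())
    }

    gold_truth <- truth[truth$kind == "gold", , drop = FALSE]
    gold_text <- substring(free_text[match(gold_truth$note_id, note_id)],
                           gold_truth$start + 1L, gold_truth$end)
    gold <- if (nrow(gold_truth) == 0) empty_exemplars() else tibble::tibble(
      exemplar_id = gold_truth$exemplar_id,
      note_id = gold_truth$note_id,
      text = gold_text,
      n_sentences = as.integer(gold_truth$last_sentence -
                                 gold_truth$first_sentence + 1L),
      category = gold_truth$category,
      provenance = "human_initial",
      annotator_ids = rep(list(character()), nrow(gold_truth)))
    gold <- gold[order(gold$exemplar_id), , drop = FALSE]
    validate_notes(notes)
    validate_exemplars(gold, corpus = notes)
    list(notes = notes, gold = gold, truth = truth)
  })
}

#' Simulated human verification of a review queue
#'
#' Stands in for the annotators who check retrieval candidates: a
#' candidate is accepted exactly when its sentence window overlaps a
#' ground-truth span of a substantive category in the same note (the
#' accepted label is the true category, recorded as an override when it
#' differs from the proposed one), and each decision is flipped with
#' probability `error_rate`.
#'
#' @param queue A [make_review_queue()] tibble.
#' @param truth Ground-truth span table from [generate_corpus()].
#' @param error_rate Probability of flipping a decision.
#' @param seed Flip seed.
#' @param known_note_ids Optional vector of valid note ids; queue rows
#'   referencing other notes raise an error.
#' @return The queue with `decision` and `override_category` filled.
#' @export
simulate_verifier <- function(queue, truth, error_rate = 0, seed = 1L,
                              known_note_ids = NULL) {
  stopifnot(error_rate >= 0, error_rate <= 1)
  if (!is.null(known_note_ids)) {
    bad <- setdiff(queue$note_id, known_note_ids)
    if (length(bad) > 0) {
      stop("review queue references unknown note(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  true_cat <- rep(NA_character_, nrow(queue))
  for (i in seq_len(nrow(queue))) {
    hits <- truth[truth$note_id == queue$note_id[i] &
                    truth$first_sentence <= queue$last_sentence[i] &
                    truth$last_sentence >= queue$first_sentence[i], ,
                  drop = FALSE]
    if (nrow(hits) > 0) true_cat[i] <- hits$category[1]
  }
  accept <- !is.na(true_cat)
  with_seed(seed, {
    flip <- stats::runif(nrow(queue)) < error_rate
    accept <- xor(accept, flip)
  })
  out <- queue
  out$decision <- ifelse(
    accept,
    ifelse(!is.na(true_cat) & true_cat != out$proposed_category,
           "accept_with_category", "accept"),
    "reject")
  out$override_category <- ifelse(out$decision == "accept_with_category",
                                  true_cat, NA_character_)
  out
}
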