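# Builds the canonical HEAR-COMMAND item-bank configuration shipped in
# inst/extdata/item_bank.json.  Run from the package root:
#   Rscript data-raw/build_item_bank.R
# Memberships (construct labels, EFA factors, score groups, polarity, gating)
# are frozen here; the package validates but never recomputes them.

short_concept <- c(
  "Mood swings", "Sleeping", "Focusing attention", "Maintaining focus",
  "Remember information", "Recall new information", "Sadness or depression",
  "Seeing across the road", "Seeing over an arm length", "Taste loss",
  "Smell loss", "Dizziness", "Loss of balance", "Pain (general)",
  "Pain (head & neck)", "Understanding meaning of a message",
  "Producing a meaningful message", "Ringing/buzzing in ears",
  "Pressure in ear", "Irritation in ear", "Distinguishing pitch",
  "Distinguishing tone", "Distinguishing volume",
  "Detecting a sound in environment", "Detecting noise in household",
  "Discriminating the sound of a car/bus", "Recognizing musical instruments",
  "Detecting where a sound comes from",
  "Telling a bus/truck is getting close or far",
  "Detecting corner of a room when one is talking",
  "Telling how far away a bus/truck is",
  "Telling where a human is when he screams/dog barks",
  "Detecting whether the person on left/right starts talking",
  "Hearing a single jumbled sound when hearing more than one sound",
  "Understanding the speech over distance",
  "Understanding the speech in a quiet environment",
  "Understanding the speech in a noisy environment",
  "Understanding news presenter on TV",
  "Understanding what one is saying while the TV is on",
  "Understanding the news presenter and someone else",
  "Having health conditions causing speech impairment",
  "Making sounds other than speech",
  "Changing pitch of sounds other than speech",
  "Changing volume of sounds other than speech", "Pronunciation",
  "Regulating the volume of speech", "Regulating the speed of speech",
  "Telling stories or reporting", "Dealing with stressful situations",
  "Interacting with people in a socially appropriate way",
  "Socializing with people in your community", "Dealing with unknown people",
  "Having formal relationships with people in authority",
  "Socializing with your family or friends", "Making new friends",
  "Having an argument or debate",
  "Understanding a statement during communication",
  "Maintaining relationships with immediate family",
  "Joining in community activities",
  "Engaging in any hobby or pleasurable activity",
  "Continuing relationships in an appropriate manner",
  "Performing communication techniques", "Your day-to-day tasks",
  "Doing your most important tasks well", "Getting done all the tasks",
  "Getting your tasks done quickly",
  "Conversation or speaking with someone",
  "Conversation or speaking with many people",
  "Carrying on a conversation during a crowded meeting",
  "Carrying on a conversation in a bus or car",
  "Following a conversation in a busy restaurant",
  "Carrying a phone call in a quiet room",
  "Telling what one is saying when conversation switches",
  "Listening to the TV/Radio/Music", "Support received from society",
  "Emotional support from family/friends",
  "Support from family/friends in daily functioning",
  "Support from health services/systems",
  "Support from healthcare professional",
  "Communication services/systems usefulness",
  "Design of workplace as a barrier", "Insufficient light as a barrier",
  "Low volume of speech as a barrier", "Background noise as a barrier",
  "Reverberant environment as a barrier",
  "Unclear sound considered a barrier",
  "Hearing aid usefulness in normal daily routines",
  "Hearing aid usefulness in conversation activities",
  "Hearing aid usefulness while using phone",
  "Hearing aid usefulness while watching TV")
stopifnot(length(short_concept) == 90)

# EFA factor per item (pattern-matrix block membership; cross-loading items
# kept with the factor of their largest loading, matching the label blocks)
factor_of <- rep(NA_integer_, 90)
factor_of[c(18, 19, 21:35, 38, 39, 73)] <- 1L
factor_of[c(7, 49:56, 58:61, 63:66, 81)] <- 2L
factor_of[83:86] <- 3L
factor_of[75:80] <- 4L
factor_of[c(37, 40, 57, 68:71)] <- 5L
factor_of[c(8, 9, 20)] <- 6L
factor_of[1:6] <- 7L
factor_of[c(12, 13)] <- 8L
factor_of[c(10, 11)] <- 9L
factor_of[c(14, 15)] <- 10L
factor_of[c(16, 17)] <- 11L
factor_of[c(62, 67, 72, 82)] <- 12L
factor_of[c(36, 74)] <- 13L

label_of_factor <- c("A", "B", "C", "D", "E", "F", "G", "F", "F", "F",
                     "G", "E", "E")
construct <- ifelse(is.na(factor_of), "NONE", label_of_factor[factor_of])

icf_domain <- c(rep("BF", 48), rep("AP", 26), rep("EF", 16))

codes <- vector("list", 90)
codes[[1]] <- "b126"; codes[[2]] <- "b134"
codes[[3]] <- c("b140", "d160"); codes[[4]] <- c("b140", "d160")
codes[[5]] <- "b144"; codes[[6]] <- "b144"; codes[[7]] <- "b152"
codes[[8]] <- "b210"; codes[[9]] <- "b210"; codes[[10]] <- "b250"
codes[[11]] <- "b255"; codes[[12]] <- "b240"; codes[[13]] <- "b240"
codes[[14]] <- "b280"; codes[[15]] <- "b280"; codes[[16]] <- "b167"
codes[[17]] <- "b167"; codes[[18]] <- "b240"; codes[[19]] <- "b240"
codes[[20]] <- "b240"
for (i in c(21, 22, 23, 35, 36, 37)) codes[[i]] <- "b1560"
codes[[24]] <- "b2300"; codes[[25]] <- "b2300"
for (i in c(26, 27, 34)) codes[[i]] <- "b2301"
for (i in 28:32) codes[[i]] <- "b2302"
codes[[33]] <- "b2303"
for (i in 38:40) codes[[i]] <- "b2304"
codes[[49]] <- "d240"; codes[[50]] <- "d710"; codes[[51]] <- "d750"
codes[[52]] <- "d730"; codes[[53]] <- "d740"; codes[[54]] <- "d750"
codes[[55]] <- "d750"; codes[[56]] <- "d355"; codes[[57]] <- "d310"
codes[[58]] <- "d760"; codes[[59]] <- "d910"; codes[[60]] <- "d920"
codes[[61]] <- "d720"; codes[[62]] <- "d360"
for (i in 63:66) codes[[i]] <- c("d220", "d820", "d830", "d850", "d855")
codes[[67]] <- c("d3500", "d3501", "d3502", "d3503")
codes[[68]] <- c("d3500", "d3501", "d3502", "d3504")
codes[[69]] <- "d3503"; codes[[70]] <- "d3503"; codes[[71]] <- "d3504"
codes[[72]] <- "d360"; codes[[73]] <- "d3503"; codes[[74]] <- "d115"
codes[[75]] <- "e460"; codes[[76]] <- c("e410", "e420")
codes[[77]] <- c("e310", "e320"); codes[[78]] <- "e580"
codes[[79]] <- "e355"; codes[[80]] <- "e535"; codes[[81]] <- "e150"
codes[[82]] <- "e240"; codes[[83]] <- "e2500"
for (i in 84:86) codes[[i]] <- "e2501"
for (i in c(41:48, 87:90)) codes[[i]] <- character(0)

speech_excluded <- c(25, 26, 27, 29, 31)  # non-speech target sounds
hearing <- construct %in% c("A", "C", "E")
non_hearing <- construct %in% c("B", "D", "F", "G")
speech <- hearing & !(seq_len(90) %in% speech_excluded)

gate <- rep("NONE", 90)
gate[42:48] <- "SPEECH_IMPAIRMENT"
gate[87:90] <- "HEARING_AID_USER"

polarity <- rep("STANDARD", 90)
polarity[75:80] <- "MIRRORED"

items <- lapply(seq_len(90), function(i) {
  list(
    id = sprintf("H.%d", i),
    icf_domain = icf_domain[i],
    icf_codes = codes[[i]],
    construct_label = construct[i],
    efa_factor = if (is.na(factor_of[i])) "NONE" else factor_of[i],
    polarity = polarity[i],
    in_hearing_related = hearing[i],
    in_non_hearing_related = non_hearing[i],
    in_speech_perception = speech[i],
    gate = gate[i],
    short_concept = short_concept[i]
  )
})

bank <- list(version = "1.0", language_tag = "en", items = items)
jsonlite::write_json(bank, "inst/extdata/item_bank.json",
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)
cat("wrote", length(items), "items\n")
cat("hearing:", sum(hearing), "non-hearing:", sum(non_hearing),
    "speech:", sum(speech), "labelled:", sum(construct != "NONE"), "\n")
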