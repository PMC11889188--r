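# Build inst/extdata/wordlist.tsv: the fixed generator vocabulary.
# Columns: token, scale. Within a loaded scale, tokens are ordered from the
# low extreme to the high extreme of that scale (the default truth assigns
# evenly spaced loadings by this order).

tmp_low <- c(
  "freezing","baltic","arctic","glacial","subzero","frigid","icy","frosty",
  "sleet","blizzard","snowing","snowy","shivering","shivery","bitter","nippy",
  "parky","chilly","chillier","wintry","frostbite","icicle","defrost","gritted",
  "numb","gloves","scarf","bracing","brisk","cooler")
tmp_high <- c(
  "warmish","warm","warmer","balmy","sunny","sunshine","sunbathe","tanning",
  "paddling","icecream","lollies","shorts","sandals","barbecue","bbq","heat",
  "hot","hotter","heatwave","sweaty","sweating","sweltering","roasting","baking",
  "boiling","blistering","tropical","stifling","scorching","scorchio")
prc_low <- c(
  "drought","parched","arid","dry","drier","driest","dusty","rainless",
  "cloudless","settled","hosepipe","reservoir","cracked","wilting","sprinkler",
  "dew","dewy","mist","misty","drizzly","drizzle","spitting","spotting",
  "shower","showery","damp","dampish","dank","soggy","sodden")
prc_high <- c(
  "raining","rainy","rain","wet","wetter","soaked","soaking","drenched",
  "saturated","puddle","puddles","umbrella","brolly","waterproofs","wellies",
  "downpour","pouring","lashing","chucking","bucketing","torrential","deluge",
  "monsoon","flood","flooding","floods","flooded","waterlogged","submerged",
  "biblical")
hum_low <- c(
  "refreshing","airy","breathable","crisp","crisper","freshened","freshening",
  "cooling","dryness","evaporated","ventilated","breezeless","dehumidified",
  "aired","airing","freshness","comfortable","unsticky","lightair","clearair",
  "coolish","pleasanter","breathed","easier","lighter","drying","driness",
  "unclammy","fresher","freshest")
hum_high <- c(
  "humid","humidity","muggy","muggier","mugginess","sticky","stickier",
  "clammy","clamminess","airless","stuffy","oppressive","soupy","sultry",
  "steamy","steaming","sauna","greenhouse","perspiring","frizzy","frizz",
  "sweatier","sweatbox","suffocating","tacky","thick","heavyair","damper",
  "humidest","tropic")
wnd_low <- c(
  "still","stillness","calm","calmer","calmest","windless","becalmed",
  "motionless","flat","glassy","placid","tranquil","serene","unruffled",
  "gentle","lull","lulled","quiet","hushed","slack","faint","languid",
  "drifting","wafting","idle","limp","sluggish","soft","light","breathless")
wnd_high <- c(
  "breeze","breezy","gust","gusts","gusty","blowy","blustery","blustering",
  "windy","windier","windiest","squall","squally","howling","whistling",
  "battering","buffeting","blowing","blown","gale","gales","galeforce",
  "storm","stormy","tempest","cyclone","hurricane","twister","windswept",
  "uprooted")
prs_low <- c(
  "depression","cyclonic","unsettled","changeable","turbulent","volatile",
  "brooding","lowering","ominous","thundery","thunder","lightning","thunders",
  "rumbling","electrical","frontal","troughs","trough","plunging","deepening",
  "unstable","churning","restless","disturbed","wild","threatening","looming",
  "menacing","angry","boiling2")
prs_high <- c(
  "anticyclone","anticyclonic","ridge","stable","steady","stagnant",
  "inversion","haze","hazy","smog","fog","foggy","murky","murk","grey",
  "greyer","greyest","overcast","dull","duller","dullest","leaden","flatlight",
  "gloaming","lid","sluggishair","heavy","pressing","dense","smothering")
sent_neg <- c(
  "terrible","horrible","awful","horrid","dreadful","miserable","misery",
  "depressing","depressed","gloom","gloomy2","grim","rubbish","dismal",
  "atrocious","abysmal","appalling","horrendous","vile","nasty","foul",
  "lousy","crappy","moan","moaning","fedup","annoying","irritating","dreary",
  "meh")
sent_pos <- c(
  "okay","alright","decent","nice","nicer","pleasing","pleasant","enjoyable",
  "enjoying","good","happy","happier","cheerful","cheery","delight",
  "delightful","lovely","lovelier","beautiful","gorgeous","glorious",
  "wonderful","fabulous","brilliant","amazing","stunning","superb",
  "excellent","joy","bliss")
emoji_neg <- c("\U0001F62D", "\U0001F621", "\U0001F631", "\U0001F327\UFE0F",
               "\U0001F4A8")
emoji_pos <- c("\U0001F642", "\U0001F60E", "\U0001F31E", "\U0001F600",
               "\U0001F60D")

# fix the two placeholder dupes
prs_low[prs_low == "boiling2"] <- "seething"
sent_neg[sent_neg == "gloomy2"] <- "woeful"

# neutral filler: common function/content words plus pronounceable pseudo-words
common <- c(
  "the","and","a","to","of","in","it","is","was","for","on","that","with","at",
  "this","as","but","be","are","have","had","we","you","they","he","she","my",
  "your","our","their","me","him","her","us","them","what","when","where",
  "which","who","how","all","any","some","more","most","other","such","only",
  "own","same","than","then","once","here","there","why","again","further",
  "about","against","between","into","through","during","before","after",
  "above","below","from","up","down","out","off","over","under","just","now",
  "today","tomorrow","yesterday","morning","afternoon","evening","week",
  "weekend","month","year","day","time","going","back","home","work","school",
  "garden","walk","walking","dog","cat","cup","tea","coffee","lunch","dinner",
  "breakfast","forecast","outside","inside","window","door","car","bus",
  "train","road","town","city","village","park","beach","hill","field",
  "river","sky","cloud","clouds","air","ground","grass","tree","trees","bird",
  "birds","people","friend","friends","family","kids","football","match",
  "game","watching","looking","seeing","thinking","feeling","saying","said",
  "got","get","getting","went","come","coming","made","make","making","know",
  "knowing","thought","really2","actually","probably","maybe","definitely",
  "finally","suddenly","slowly","quickly","nearly","almost","around","away")
common[common == "really2"] <- "supposedly"
common <- setdiff(common, c("not","no","never"))  # keep negators out of filler

set.seed(20210101)
syllables <- c("ba","be","bi","bo","bu","da","de","di","do","du","fa","fe",
  "fi","fo","fu","ga","ge","gi","go","gu","ka","ke","ki","ko","ku","la","le",
  "li","lo","lu","ma","mi","mo","mu","na","ne","ni","nu","pa","pe","pi","po",
  "pu","ra","re","ri","ro","ru","sa","se","si","su","ta","te","ti","tu","va",
  "ve","vi","vo","za","zo")
pseudo <- character(0)
while (length(pseudo) < 600) {
  w <- paste0(sample(syllables, sample(2:3, 1), replace = TRUE), collapse = "")
  pseudo <- unique(c(pseudo, w))
}

loaded <- c(tmp_low, tmp_high, prc_low, prc_high, hum_low, hum_high,
            wnd_low, wnd_high, prs_low, prs_high, sent_neg, sent_pos,
            emoji_neg, emoji_pos)
stopifnot(!anyDuplicated(loaded))
pseudo <- setdiff(setdiff(pseudo, loaded), common)
filler <- c(common, pseudo)[1:500]
stopifnot(length(filler) == 500, !anyDuplicated(filler),
          !"weather" %in% c(filler, loaded))

wl <- rbind(
  data.frame(token = filler, scale = "filler"),
  data.frame(token = c(tmp_low, tmp_high), scale = "temperature"),
  data.frame(token = c(prc_low, prc_high), scale = "precipitation"),
  data.frame(token = c(hum_low, hum_high), scale = "humidity"),
  data.frame(token = c(wnd_low, wnd_high), scale = "wind"),
  data.frame(token = c(prs_low, prs_high), scale = "pressure"),
  data.frame(token = c(sent_neg, sent_pos), scale = "sentiment"),
  data.frame(token = c(emoji_neg, emoji_pos), scale = "emoji")
)
stopifnot(!anyDuplicated(wl$token))
stopifnot(all(table(wl$scale)[c("temperature","precipitation","humidity",
  "wind","pressure","sentiment")] == 60), sum(wl$scale == "emoji") == 10)

con <- file("inst/extdata/wordlist.tsv", open = "w", encoding = "UTF-8")
writeLines("token\tscale", con)
writeLines(paste(wl$token, wl$scale, sep = "\t"), con)
close(con)
cat("wrote", nrow(wl), "tokens\n")
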