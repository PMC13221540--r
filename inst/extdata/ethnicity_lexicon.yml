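# Ethnicity normalization lexicon: 42 standardized categories across six
# geographic regions. Each category lists lowercase surface terms (including
# country/location names used by the born/raised-in identity pattern).
# Surface terms must be unique across the whole lexicon. User-extensible:
# pass an edited copy to read_ethnicity_lexicon().
categories:
  # --- European (12) ---
  british:
    region: European
    display: British
    terms: [british, english, welsh, scottish, england, scotland, wales, britain, united kingdom]
  irish:
    region: European
    display: Irish
    terms: [irish, ireland]
  french:
    region: European
    display: French
    terms: [french, france, breton, norman]
  german:
    region: European
    display: German
    terms: [german, germany, bavarian, prussian]
  italian:
    region: European
    display: Italian
    terms: [italian, italy, sicilian, sardinian, tuscan]
  spanish:
    region: European
    display: Spanish
    terms: [spanish, spain, iberian, basque, catalan, castilian]
  portuguese:
    region: European
    display: Portuguese
    terms: [portuguese, portugal, azorean]
  greek:
    region: European
    display: Greek
    terms: [greek, greece, hellenic]
  scandinavian:
    region: European
    display: Scandinavian
    terms: [scandinavian, swedish, norwegian, danish, sweden, norway, denmark, icelandic, iceland, finnish, finland, nordic]
  eastern_european:
    region: European
    display: Eastern European
    terms: [eastern european, polish, russian, ukrainian, czech, slovak, hungarian, lithuanian, latvian, estonian, belarusian, poland, russia, ukraine, hungary]
  balkan:
    region: European
    display: Balkan
    terms: [balkan, serbian, croatian, bosnian, bulgarian, albanian, macedonian, slovenian, romanian, serbia, croatia, bulgaria, albania, romania]
  jewish:
    region: European
    display: Jewish
    terms: [jewish, ashkenazi, sephardic, ashkenazi jewish, sephardic jewish]
  # --- African (7) ---
  nigerian:
    region: African
    display: Nigerian
    terms: [nigerian, yoruba, igbo, hausa, nigeria]
  west_african:
    region: African
    display: West African
    terms: [west african, senegalese, malian, ghanaian, senegal, mali, ghana, ivorian]
  east_african:
    region: African
    display: East African
    terms: [east african, ethiopian, somali, kenyan, eritrean, ethiopia, somalia, kenya, tanzanian]
  north_african:
    region: African
    display: North African
    terms: [north african, egyptian, moroccan, algerian, tunisian, berber, libyan, egypt, morocco, algeria, tunisia]
  central_african:
    region: African
    display: Central African
    terms: [central african, congolese, cameroonian, congo, cameroon, chadian]
  southern_african:
    region: African
    display: Southern African
    terms: [southern african, south african, zulu, xhosa, zimbabwean, south africa, zimbabwe]
  african_american:
    region: African
    display: African American
    terms: [african american, black american]
  # --- Asian (9) ---
  chinese:
    region: Asian
    display: Chinese
    terms: [chinese, han, han chinese, china]
  japanese:
    region: Asian
    display: Japanese
    terms: [japanese, japan, okinawan]
  korean:
    region: Asian
    display: Korean
    terms: [korean, korea]
  indian:
    region: Asian
    display: Indian
    terms: [indian, south asian, punjabi, bengali, india]
  pakistani:
    region: Asian
    display: Pakistani
    terms: [pakistani, pakistan, sindhi, pashtun, baloch]
  southeast_asian:
    region: Asian
    display: Southeast Asian
    terms: [southeast asian, thai, indonesian, thailand, indonesia, malaysian, malaysia, cambodian, laotian, burmese]
  filipino:
    region: Asian
    display: Filipino
    terms: [filipino, philippine, philippines, tagalog, visayan]
  vietnamese:
    region: Asian
    display: Vietnamese
    terms: [vietnamese, vietnam, kinh]
  central_asian:
    region: Asian
    display: Central Asian
    terms: [central asian, kazakh, uzbek, mongolian, kyrgyz, tajik, turkmen, kazakhstan, uzbekistan, mongolia]
  # --- Americas (8) ---
  native_american:
    region: Americas
    display: Native American
    terms: [native american, indigenous, cherokee, navajo, sioux, apache, first nations]
  mexican:
    region: Americas
    display: Mexican
    terms: [mexican, mestizo, mexico]
  caribbean:
    region: Americas
    display: Caribbean
    terms: [caribbean, jamaican, haitian, jamaica, haiti, puerto rican, trinidadian, cuban, dominican]
  central_american:
    region: Americas
    display: Central American
    terms: [central american, guatemalan, honduran, salvadoran, nicaraguan, panamanian, costa rican, guatemala, honduras]
  south_american:
    region: Americas
    display: South American
    terms: [south american, argentinian, argentine, chilean, colombian, venezuelan, uruguayan, paraguayan, argentina, chile, colombia, venezuela]
  andean:
    region: Americas
    display: Andean
    terms: [andean, peruvian, bolivian, ecuadorian, quechua, aymara, peru, bolivia, ecuador]
  brazilian:
    region: Americas
    display: Brazilian
    terms: [brazilian, brazil]
  inuit:
    region: Americas
    display: Inuit
    terms: [inuit, yupik, greenlandic, alaska native]
  # --- Middle Eastern (3) ---
  middle_eastern:
    region: Middle Eastern
    display: Middle Eastern
    terms: [middle eastern, arab, levantine, iraqi, syrian, lebanese, palestinian, jordanian, iraq, syria, lebanon, arabian]
  iranian:
    region: Middle Eastern
    display: Iranian
    terms: [iranian, persian, iran, persia]
  turkish:
    region: Middle Eastern
    display: Turkish
    terms: [turkish, anatolian, turkey, turk]
  # --- Oceania (3) ---
  polynesian:
    region: Oceania
    display: Polynesian
    terms: [polynesian, hawaiian, samoan, tongan, hawaii, samoa, tonga, maori]
  melanesian:
    region: Oceania
    display: Melanesian
    terms: [melanesian, fijian, papuan, papua, fiji]
  australian_aboriginal:
    region: Oceania
    display: Australian Aboriginal
    terms: [australian aboriginal, aboriginal, aboriginal australian, torres strait islander]
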