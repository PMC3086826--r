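# Name, country and hospital pools for the synthetic generator. Names are a
# compact Anglo/European mix typical of a mid-1990s Australian cohort; the
# collision pairs share a 3-letter prefix and are used to arrange
# family-member suffix clashes (the disambiguation failure mode the suffix
# cannot resolve).

given_names_male <- c(
  "JAMES", "JOHN", "ROBERT", "MICHAEL", "WILLIAM", "DAVID", "RICHARD",
  "THOMAS", "CHARLES", "PETER", "KENNETH", "STEVEN", "EDWARD", "BRIAN",
  "RONALD", "ANTHONY", "KEVIN", "JASON", "MATTHEW", "GARY", "TIMOTHY",
  "LARRY", "JEFFREY", "FRANK", "SCOTT", "ERIC", "STEPHEN", "ANDREW",
  "RAYMOND", "GREGORY", "JOSHUA", "DENNIS", "JERRY", "WALTER", "PATRICK",
  "HAROLD", "DOUGLAS", "HENRY", "CARL", "ARTHUR", "RYAN", "ROGER", "JOE",
  "ALBERT", "JONATHAN", "JUSTIN", "TERRY", "GERALD", "KEITH", "LAWRENCE",
  "SEAN", "CHRISTOPHER", "SAMUEL", "ALEXANDER", "FRANCIS", "DANIEL",
  "NICHOLAS", "JOSEPH", "GEORGE", "GABRIEL", "BRUCE", "BARRY", "NEIL",
  "GRAHAM", "IAN", "COLIN", "TREVOR", "WAYNE", "GIOVANNI", "ANTONIO",
  "STAVROS", "DIMITRI", "MARCO", "LUIGI", "NGUYEN", "WEI"
)

given_names_female <- c(
  "MARY", "LINDA", "BARBARA", "ELIZABETH", "JENNIFER", "MARIA", "SUSAN",
  "MARGARET", "DOROTHY", "LISA", "NANCY", "KAREN", "BETTY", "HELEN",
  "SANDRA", "DONNA", "CAROL", "RUTH", "SHARON", "MICHELLE", "LAURA",
  "SARAH", "KIMBERLY", "DEBORAH", "JESSICA", "SHIRLEY", "CYNTHIA",
  "ANGELA", "MELISSA", "BRENDA", "AMY", "ANNA", "REBECCA", "VIRGINIA",
  "KATHLEEN", "PAMELA", "MARTHA", "DEBRA", "AMANDA", "STEPHANIE",
  "CAROLYN", "CHRISTINE", "MARIE", "JANET", "CATHERINE", "FRANCES",
  "ANN", "JOYCE", "DIANE", "ALICE", "ALISON", "SAMANTHA", "ALEXANDRA",
  "DANIELLE", "NICOLA", "JOSEPHINE", "GEORGIA", "GABRIELLA", "PATRICIA",
  "JULIE", "VALERIE", "GLENDA", "SOFIA", "ELENA", "GINA", "CARLA",
  "ROSA", "THI", "MEI"
)

# pairs sharing a 3-letter prefix, (male, female)
collision_name_pairs <- list(
  c("CHRISTOPHER", "CHRISTINE"),
  c("PATRICK", "PATRICIA"),
  c("SAMUEL", "SAMANTHA"),
  c("ALEXANDER", "ALEXANDRA"),
  c("FRANCIS", "FRANCES"),
  c("DANIEL", "DANIELLE"),
  c("NICHOLAS", "NICOLA"),
  c("JOSEPH", "JOSEPHINE"),
  c("GEORGE", "GEORGIA"),
  c("GABRIEL", "GABRIELLA")
)

country_pool <- c(
  "AUSTRALIA", "UNITED KINGDOM", "ITALY", "GREECE", "NEW ZEALAND",
  "MALTA", "NETHERLANDS", "GERMANY", "VIETNAM", "CHINA"
)
country_weights <- c(0.66, 0.10, 0.08, 0.06, 0.03, 0.02, 0.02, 0.01, 0.01,
                     0.01)

hospital_pool <- c(
  "ROYAL MELBOURNE HOSPITAL", "ALFRED HOSPITAL", "MONASH MEDICAL CENTRE",
  "ST VINCENTS HOSPITAL", "AUSTIN HOSPITAL", "BOX HILL HOSPITAL",
  "GEELONG HOSPITAL", "FRANKSTON HOSPITAL", "NORTHERN HOSPITAL",
  "SUNSHINE HOSPITAL", "EPWORTH HOSPITAL", "CABRINI HOSPITAL"
)
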