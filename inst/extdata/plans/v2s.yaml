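label: v2s
iterations:
- label: suf+dob+sex+cob.pc1
  selectors:
  - suffix
  - birth_year
  - birth_month
  - birth_day
  - sex
  - country_of_birth
  - postcode1
- label: suf+dob+sex+cob.pc2
  selectors:
  - suffix
  - birth_year
  - birth_month
  - birth_day
  - sex
  - country_of_birth
  - postcode2
- label: suf+dob+sex+cob.pc3
  selectors:
  - suffix
  - birth_year
  - birth_month
  - birth_day
  - sex
  - country_of_birth
  - postcode3
- label: suf+dob+sex+cob.pc4
  selectors:
  - suffix
  - birth_year
  - birth_month
  - birth_day
  - sex
  - country_of_birth
  - postcode4
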