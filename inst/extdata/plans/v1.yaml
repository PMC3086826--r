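label: v1
iterations:
- label: m8+suf
  selectors:
  - medicare8
  - suffix
- label: m8+suf12+sex
  selectors:
  - medicare8
  - suffix_12
  - sex
- label: m8+suf23+sex
  selectors:
  - medicare8
  - suffix_23
  - sex
- label: m8+suf13+sex
  selectors:
  - medicare8
  - suffix_13
  - sex
- label: m8+year+sex
  selectors:
  - medicare8
  - birth_year
  - sex
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
- label: dob+sex+cob.pc1
  selectors:
  - birth_year
  - birth_month
  - birth_day
  - sex
  - country_of_birth
  - postcode1
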