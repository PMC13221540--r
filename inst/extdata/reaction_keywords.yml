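# Six-category reaction classification keywords. Phrases are matched
# case-insensitively with whole-word/phrase boundaries; apostrophe variants
# ("don't"/"dont") both match. A phrase may appear under only one category.
surprise:
  - surprised
  - shocking
  - shocked
  - unexpected
  - never expected
  - no idea
  - mind blown
  - wow
  - crazy
  - wild
  - insane
  - unbelievable
dispute:
  - wrong
  - incorrect
  - inaccurate
  - mistake
  - error
  - fake
  - scam
  - don't believe
  - doubt
  - skeptical
  - no way
  - impossible
acceptance:
  - makes sense
  - expected
  - confirmed
  - accurate
  - correct
  - exactly what
  - as expected
  - no surprises
  - knew it
  - matches
disappointment:
  - disappointed
  - disappointing
  - wished
  - hoped for
  - wanted to be
  - thought i was
  - boring
  - basic
  - generic
  - letdown
identity_crisis:
  - identity crisis
  - who am i
  - don't know who
  - existential
  - questioning
  - lied to me
  - not my real
  - npe
  - adoption
excitement:
  - excited
  - amazing
  - awesome
  - love
  - cool
  - fascinating
  - interesting
  - incredible
  - wonderful
  - thrilled
  - happy
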