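synonym	canonical
nadh dehydrogenase subunit 1	ndhA
nadh dehydrogenase subunit 2	ndhB
nadh dehydrogenase subunit 3	ndhC
nadh dehydrogenase subunit 4	ndhD
nadh dehydrogenase subunit 4l	ndhE
nadh dehydrogenase subunit 5	ndhF
nadh dehydrogenase subunit 6	ndhG
nadh dehydrogenase subunit 7	ndhH
nadh dehydrogenase subunit i	ndhI
nadh dehydrogenase subunit j	ndhJ
nadh dehydrogenase subunit k	ndhK
nadh-plastoquinone oxidoreductase subunit 1	ndhA
nadh-plastoquinone oxidoreductase subunit 2	ndhB
nadh-plastoquinone oxidoreductase subunit 3	ndhC
nadh-plastoquinone oxidoreductase subunit 4	ndhD
nadh-plastoquinone oxidoreductase subunit 4l	ndhE
nadh-plastoquinone oxidoreductase subunit 5	ndhF
nadh-plastoquinone oxidoreductase subunit 6	ndhG
nadh-plastoquinone oxidoreductase subunit 7	ndhH
nadh-plastoquinone oxidoreductase subunit i	ndhI
nadh-plastoquinone oxidoreductase subunit j	ndhJ
nadh-plastoquinone oxidoreductase subunit k	ndhK
ndh1	ndhA
ndh2	ndhB
ndh3	ndhC
ndh4	ndhD
ndh4l	ndhE
ndh5	ndhF
ndh6	ndhG
ndh7	ndhH
ndh-a	ndhA
ndh-b	ndhB
ndh-c	ndhC
ndh-d	ndhD
ndh-e	ndhE
ndh-f	ndhF
ndh-g	ndhG
ndh-h	ndhH
ndh-i	ndhI
ndh-j	ndhJ
ndh-k	ndhK
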