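id,sex,identity_known,age_group,year,day_type,season,region,urban_rural,injury_category,alcohol,place,cause_class
1,male,yes,65+,2003,other,summer,siberia,urban,17,no,residential_institution,SUI
2,male,yes,35-44,2001,postholiday_monday,winter,siberia,urban,18,yes,home,NTA
3,female,yes,65+,2010,other,winter,moscow,rural,15,yes,unspecified,EUI
4,male,yes,65+,2003,other,winter,moscow,rural,18,yes,unspecified,NTA
5,male,yes,65+,2003,postholiday_monday,winter,south,urban,13,yes,home,EUI
6,male,yes,unknown,2001,postholiday_monday,summer,northwest,rural,14,no,home,NTA
7,male,yes,55-64,2006,other,winter,moscow,urban,18,yes,home,EUI
8,male,yes,25-34,2008,other,spring_autumn,fareast,rural,5,yes,other_specified,EUI
9,male,yes,25-34,2007,postholiday_monday,spring_autumn,northcaucasus,rural,17,yes,other_specified,NTA
10,male,yes,35-44,2002,postholiday_monday,spring_autumn,moscow,urban,14,no,unspecified,NTA
11,male,yes,45-54,2010,other,summer,moscow,urban,13,yes,trade_service,NTA
12,male,yes,45-54,2005,other,winter,siberia,urban,17,no,home,SUI
13,male,yes,35-44,2007,other,winter,fareast,urban,13,no,other_specified,NTA
14,male,yes,unknown,2003,postholiday_monday,winter,fareast,urban,6,yes,other_specified,EUI
15,female,yes,25-34,2003,postholiday_monday,spring_autumn,northwest,urban,8,yes,home,NTA
16,male,yes,65+,2011,other,summer,fareast,urban,14,no,other_specified,NTA
17,male,yes,65+,2004,other,winter,siberia,rural,18,no,other_specified,NTA
18,female,yes,55-64,2008,other,summer,volga,rural,18,no,other_specified,EUI
19,male,yes,15-24,2001,other,summer,northcaucasus,urban,14,yes,street_highway,NTA
20,male,yes,65+,2011,other,winter,south,urban,18,no,home,NTA
21,male,yes,65+,2009,other,winter,northwest,rural,18,no,home,NTA
22,male,yes,45-54,2006,other,winter,volga,rural,8,no,street_highway,NTA
23,male,yes,65+,2008,other,spring_autumn,siberia,urban,8,yes,home,NTA
24,female,yes,55-64,2001,other,spring_autumn,ural,urban,18,yes,other_specified,NTA
25,male,yes,55-64,2000,other,winter,fareast,urban,10,yes,other_specified,NTA
26,female,yes,65+,2000,postholiday_monday,winter,ural,urban,18,no,sports,NTA
27,female,yes,25-34,2011,postholiday_monday,winter,northwest,rural,12,yes,unspecified,EUI
28,female,yes,35-44,2006,other,spring_autumn,northwest,rural,14,yes,unspecified,NTA
29,male,yes,55-64,2001,other,summer,volga,urban,12,yes,home,NTA
30,female,yes,25-34,2001,other,spring_autumn,northwest,urban,14,no,unspecified,NTA
31,male,yes,55-64,2008,postholiday_monday,spring_autumn,central,urban,7,no,street_highway,HOM
32,male,yes,45-54,2001,postholiday_monday,winter,volga,urban,1,no,other_specified,NTA
33,male,yes,55-64,2006,other,summer,volga,urban,17,yes,other_specified,SUI
34,female,yes,55-64,2003,other,spring_autumn,central,urban,18,no,home,NTA
35,male,yes,15-24,2000,other,winter,ural,urban,16,yes,other_specified,EUI
36,male,yes,15-24,2007,other,summer,ural,rural,18,yes,other_specified,NTA
37,female,yes,unknown,2001,other,summer,south,urban,13,yes,home,NTA
38,male,yes,55-64,2008,other,winter,central,urban,13,yes,home,EUI
39,male,yes,55-64,2007,other,spring_autumn,volga,urban,15,no,home,SUI
40,male,yes,65+,2003,other,spring_autumn,central,urban,18,no,other_specified,NTA
41,male,yes,45-54,2010,other,summer,ural,urban,15,yes,home,NTA
42,female,yes,25-34,2007,other,winter,ural,urban,1,yes,street_highway,HOM
43,male,yes,15-24,2007,other,spring_autumn,volga,urban,13,no,trade_service,NTA
44,male,yes,35-44,2001,other,summer,moscow,urban,16,yes,home,NTA
45,female,yes,45-54,2002,other,winter,siberia,urban,14,no,street_highway,EUI
46,male,yes,45-54,2001,other,spring_autumn,northwest,urban,13,yes,home,NTA
47,male,yes,25-34,2009,other,summer,central,urban,2,yes,unspecified,HOM
48,male,yes,25-34,2004,other,winter,central,urban,11,no,home,NTA
49,male,yes,65+,2002,other,winter,siberia,urban,16,no,home,NTA
50,male,yes,65+,2004,postholiday_monday,summer,south,urban,18,yes,unspecified,NTA
51,female,yes,45-54,2000,other,winter,ural,urban,7,no,street_highway,EUI
52,male,yes,15-24,2000,postholiday_monday,spring_autumn,fareast,rural,17,no,other_specified,SUI
53,female,yes,65+,2003,other,summer,moscow,rural,5,yes,home,HOM
54,male,yes,65+,2000,other,summer,ural,urban,6,yes,street_highway,EUI
55,female,yes,55-64,2005,other,spring_autumn,siberia,rural,10,yes,unspecified,NTA
56,male,yes,35-44,2004,other,winter,northwest,urban,17,no,home,SUI
57,female,yes,65+,2008,other,spring_autumn,northwest,rural,4,no,home,SUI
58,male,yes,45-54,2010,other,spring_autumn,fareast,rural,13,no,other_specified,NTA
59,female,yes,25-34,2006,other,spring_autumn,northcaucasus,urban,1,yes,other_specified,HOM
60,male,yes,65+,2008,other,summer,central,urban,14,yes,street_highway,NTA
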