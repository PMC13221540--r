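word,polarity,subjectivity
love,0.50,0.60
loved,0.70,0.80
amazing,0.60,0.90
awesome,1.00,1.00
wonderful,1.00,1.00
excellent,1.00,1.00
excited,0.38,0.75
exciting,0.45,0.80
happy,0.80,1.00
thrilled,0.60,0.90
delighted,0.90,1.00
fascinating,0.60,0.85
interesting,0.50,0.50
incredible,0.90,0.90
cool,0.35,0.65
great,0.80,0.75
good,0.70,0.60
nice,0.60,1.00
glad,0.50,1.00
enjoyed,0.50,0.60
fun,0.30,0.20
beautiful,0.85,1.00
best,1.00,0.30
better,0.50,0.50
helpful,0.40,0.30
pleased,0.55,0.90
pleasant,0.70,0.80
perfect,1.00,1.00
impressive,0.90,1.00
satisfied,0.50,0.70
proud,0.60,0.80
brilliant,0.90,0.95
lovely,0.75,0.95
positive,0.35,0.55
easy,0.43,0.83
accurate,0.30,0.40
correct,0.25,0.40
fine,0.42,0.45
surprised,0.25,0.70
surprising,0.25,0.80
curious,0.25,0.70
hopeful,0.40,0.70
relieved,0.35,0.75
fair,0.35,0.60
new,0.14,0.45
old,0.10,0.25
long,-0.05,0.40
short,0.00,0.35
wrong,-0.50,0.55
incorrect,-0.40,0.60
inaccurate,-0.45,0.70
fake,-0.55,0.75
scam,-0.80,0.90
skeptical,-0.30,0.70
impossible,-0.60,0.75
disappointed,-0.60,0.80
disappointing,-0.60,0.80
boring,-1.00,1.00
terrible,-1.00,1.00
awful,-1.00,1.00
bad,-0.70,0.67
horrible,-1.00,1.00
sad,-0.50,1.00
unhappy,-0.60,0.90
angry,-0.50,0.90
upset,-0.45,0.85
annoying,-0.60,0.90
frustrating,-0.55,0.85
frustrated,-0.55,0.85
hate,-0.80,0.90
worst,-1.00,1.00
useless,-0.50,0.60
confusing,-0.40,0.75
confused,-0.35,0.75
worried,-0.40,0.80
crazy,-0.30,1.00
insane,-0.40,1.00
broken,-0.40,0.60
slow,-0.30,0.40
waste,-0.55,0.65
poor,-0.60,0.70
misleading,-0.55,0.80
painful,-0.70,0.90
stressful,-0.50,0.85
scared,-0.55,0.90
personal,0.10,0.70
honest,0.40,0.75
simple,0.15,0.45
strange,-0.15,0.80
odd,-0.20,0.75
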