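## General Information
1. Can you confirm your full name for our records?
2. What is your date of birth?
3. What is your current address?
4. What is your occupation at the moment?
5. How would you describe your ethnic or cultural background?
6. What is your relationship status right now?
7. Do you have any children?
8. What brings you in to see us today?
9. When did the concerns that bring you in first start?
10. How have these concerns affected your day-to-day functioning?

## Medical History
1. Are you currently taking any prescribed medications?
2. Do you have any allergies we should know about?
3. Do you take any health supplements regularly?
4. Do you use any recreational drugs or alcohol?
5. Have you ever been hospitalized for a mental health concern?
6. Have you received any psychiatric diagnoses in the past?
7. Have you ever attended counselling or psychotherapy before?
8. How has your sleep been over the past month?
9. How has your appetite been recently?
10. Have you noticed changes in your energy or motivation?
11. Have you had any significant physical illnesses or injuries?
12. Have you ever had thoughts of harming yourself or others?

## Family History
1. Is there any history of mental illness in your family?
2. Is there any history of substance use problems in your family?
3. How would you describe your relationship with your parents?
4. Do you have siblings, and how do you get along with them?
5. Who were you raised by, and where did you grow up?
6. Are there any significant medical conditions that run in your family?
7. How often are you in contact with your extended family?
8. Were there any major disruptions in your family while you were growing up?

## Personal History
1. Can you walk me through your work history?
2. Have you had any past marriages or significant relationships?
3. What do you usually do to relax or unwind?
4. What are your main interests or hobbies?
5. How would you describe your social circle and friendships?
6. How far did you go in school, and how was that experience?
7. Can you describe a typical day in your life at the moment?
8. How do you usually cope when you are under stress?
9. Have you experienced any events you would describe as traumatic?
10. Have there been any major losses in your life recently?
11. What does your exercise or physical activity look like?
12. Are you part of any community, religious, or cultural groups?
13. What goals or plans are important to you right now?
14. Is there anything about your living situation that causes you stress?

## Additional Comments
1. Is there anything we have not covered that you would like to mention?
2. Do you have any questions or concerns about what happens next?
3. Before we finish, is there anything else you would like to add today?
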